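# Synthetic camera-trap surveys.
#
# The generator mirrors the survey design the models assume: 73 grid-cell
# sites carrying 1-4 camera replicates (143 cameras in total), 15 three-day
# occasions, detection probability around 0.06-0.08, mean site abundance
# around 2-3, and standardized site covariates with modest effect sizes.
# Truth defaults are the Poisson point estimates of the motivating survey,
# so "can the pipeline recover that world" is the canonical validation.

# deterministic replicate allocation: 73 sites, 143 cameras, 1-4 per site
default_replicates <- function(n_sites) {
  base <- rep(rep(1:4, times = c(25, 31, 12, 5)), length.out = n_sites)
  base
}

default_covariate_model <- function() {
  # means/SDs on natural scales comparable to the survey's covariate table
  data.frame(
    name = c("mixed", "sal.forest", "human_CR", "vildist", "fruit_density",
             "Agricultural.land"),
    mean = c(6.0, 2.0, 2.2, 4.0, 0.03, 3.0),
    sd = c(3.0, 1.5, 2.6, 3.0, 0.02, 2.5),
    stringsAsFactors = FALSE)
}

#' Configuration of a synthetic camera-trap survey
#'
#' Bundles the design (sites, replicates, occasions), the generative truth
#' (link-scale coefficients of the abundance and detection predictors, plus
#' mixture-specific parameters) and the covariate model.  Defaults
#' reproduce the shape of the motivating survey: 73 sites, 1-4 replicates
#' (143 cameras), 15 occasions of 3 days, `log(lambda)` intercept 0.95 with
#' effects 0.33/0.27/0.25/0.21 of mixed forest, human capture rate,
#' village distance and sal forest, and `logit(p)` intercept `qlogis(0.08)`
#' with a 0.27 effect of fruiting-tree density.
#'
#' @param n_sites number of sites.
#' @param replicates integer scalar or per-site vector of camera replicates
#'   (1-4); default allocates 143 cameras over 73 sites.
#' @param n_occasions,occasion_length_days temporal design.
#' @param mixture generating abundance mixture (`"P"`, `"NB"`, `"ZIP"`).
#' @param state_coefs named abundance coefficients (must include
#'   `"(Intercept)"`); names refer to covariates.
#' @param det_coefs named detection coefficients, same convention.
#' @param nb_alpha NB dispersion (used when `mixture = "NB"`).
#' @param zip_psi zero-inflation probability (used when `mixture = "ZIP"`);
#'   default 0.3, the rough fraction of unoccupied sites in the survey.
#' @param covariate_model data frame `name`/`mean`/`sd` of raw covariate
#'   scales, plus optional `correlation` matrix among covariates.
#' @param correlation optional covariate correlation matrix.
#' @param start_date first deployment date for event-level simulation.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_sites = 73, replicates = NULL, n_occasions = 15,
                       occasion_length_days = 3,
                       mixture = c("P", "NB", "ZIP"),
                       state_coefs = c("(Intercept)" = 0.95, mixed = 0.33,
                                       human_CR = 0.27, vildist = 0.25,
                                       sal.forest = 0.21),
                       det_coefs = c("(Intercept)" = qlogis(0.08),
                                     fruit_density = 0.27),
                       nb_alpha = 1, zip_psi = 0.3,
                       covariate_model = default_covariate_model(),
                       correlation = NULL,
                       start_date = as.Date("2016-12-01")) {
  mixture <- match.arg(mixture)
  if (is.null(replicates)) replicates <- default_replicates(n_sites)
  replicates <- rep_len(as.integer(replicates), n_sites)
  stopifnot(all(replicates >= 1L), n_occasions >= 1, occasion_length_days >= 1)
  if (any(replicates > 4L)) warning("replicates above the design maximum of 4")
  if (!"(Intercept)" %in% names(state_coefs) ||
      !"(Intercept)" %in% names(det_coefs))
    stop("state_coefs and det_coefs must include an '(Intercept)' term")
  used <- setdiff(c(names(state_coefs), names(det_coefs)), "(Intercept)")
  missing <- setdiff(used, covariate_model$name)
  if (length(missing))
    stop("coefficients refer to covariates absent from covariate_model: ",
         paste(missing, collapse = ", "))
  structure(list(n_sites = as.integer(n_sites), replicates = replicates,
                 n_occasions = as.integer(n_occasions),
                 occasion_length_days = as.integer(occasion_length_days),
                 mixture = mixture, state_coefs = state_coefs,
                 det_coefs = det_coefs, nb_alpha = nb_alpha,
                 zip_psi = zip_psi, covariate_model = covariate_model,
                 correlation = correlation, start_date = start_date),
            class = "sim_config")
}

#' Simulate site covariates
#'
#' Draws (optionally correlated) multivariate-normal site covariates on the
#' scales given by the configuration's covariate model, then
#' Z-standardizes them.  Returns both the raw and the standardized table.
#'
#' @param config a [sim_config()].
#' @return list with elements `raw` and `standardized`
#'   ([site_covariates()] tables).
#' @export
simulate_covariates <- function(config) {
  cm <- config$covariate_model
  k <- nrow(cm)
  Sigma <- if (is.null(config$correlation)) diag(k) else config$correlation
  if (!isSymmetric(unname(Sigma)) || any(eigen(Sigma, only.values = TRUE)$values <= 0))
    stop("covariate correlation matrix must be symmetric positive definite")
  z <- MASS::mvrnorm(config$n_sites, mu = rep(0, k), Sigma = Sigma)
  raw <- sweep(sweep(z, 2, cm$sd, `*`), 2, cm$mean, `+`)
  colnames(raw) <- cm$name
  ids <- sprintf("S%03d", seq_len(config$n_sites))
  raw_tab <- site_covariates(data.frame(site_id = ids, raw,
                                        check.names = FALSE))
  list(raw = raw_tab, standardized = standardize_covariates(raw_tab))
}

#' Simulate a count matrix from the generative model
#'
#' Per site, draws the latent abundance `N_i` from the configured mixture at
#' `lambda_i = exp(X beta)`, then fills each surveyed replicate-occasion
#' cell with an independent `Binomial(N_i, p_i)` thinning at
#' `p_i = plogis(X alpha)`; cells of replicates a site does not have are
#' missing.  The latent truth is attached for recovery testing.
#'
#' @param config a [sim_config()].
#' @param covs the `standardized` table from [simulate_covariates()].
#' @return a [count_matrix()] whose `truth` component records `N`,
#'   `lambda`, `p` and the configuration.
#' @export
simulate_counts <- function(config, covs) {
  stopifnot(is_standardized(covs))
  R <- config$n_sites; Tocc <- config$n_occasions
  Xs <- build_design(covs, setdiff(names(config$state_coefs), "(Intercept)"), R)
  Xd <- build_design(covs, setdiff(names(config$det_coefs), "(Intercept)"), R)
  lambda <- as.vector(exp(Xs %*% config$state_coefs[colnames(Xs)]))
  p <- as.vector(plogis(Xd %*% config$det_coefs[colnames(Xd)]))

  N <- switch(config$mixture,
    P = rpois(R, lambda),
    NB = rnbinom(R, size = config$nb_alpha, mu = lambda),
    ZIP = ifelse(runif(R) < config$zip_psi, 0L, rpois(R, lambda)))

  max_rep <- max(config$replicates)
  m <- matrix(NA_integer_, R, max_rep * Tocc,
              dimnames = list(covs$site_id, NULL))
  for (i in seq_len(R)) {
    for (k in seq_len(config$replicates[i])) {
      cols <- (k - 1L) * Tocc + seq_len(Tocc)
      m[i, cols] <- rbinom(Tocc, size = N[i], prob = p[i])
    }
  }
  out <- count_matrix(m, n_occasions = Tocc)
  out$truth <- list(N = N, lambda = lambda, p = p, config = config)
  out
}

#' Expand counts into raw photo events and deployments
#'
#' Inverse of the preparation pipeline, for end-to-end testing: every
#' counted detection becomes a cluster of 1-3 photographs taken within less
#' than 30 minutes (so the independence filter must collapse each cluster
#' back to one event), with cluster onsets spaced at least 30 minutes apart
#' inside the correct occasion window.  Round-tripping the result through
#' [filter_independent_events()], [pool_occasions()] and
#' [aggregate_to_sites()] reproduces the input counts exactly.
#'
#' @param config a [sim_config()].
#' @param counts a [count_matrix()] from [simulate_counts()].
#' @param species species tag for the events, default `"focal"`.
#' @return list with `events` and `deployments` data frames.
#' @export
simulate_photo_events <- function(config, counts, species = "focal") {
  y <- as_count_mat(counts)
  Tocc <- config$n_occasions
  L <- config$occasion_length_days
  n_days <- Tocc * L
  start <- config$start_date
  origin <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")

  events <- list(); deps <- list(); e <- 0L
  for (i in seq_len(nrow(y))) {
    sid <- counts$site_ids[i]
    for (k in seq_len(config$replicates[i])) {
      cam <- sprintf("%s_C%d", sid, k)
      deps[[length(deps) + 1L]] <- data.frame(
        camera_id = cam, site_id = sid, active_start = start,
        active_end = start + n_days - 1L, trap_nights = n_days)
      for (t in seq_len(Tocc)) {
        n_ev <- y[i, (k - 1L) * Tocc + t]
        if (is.na(n_ev) || n_ev == 0L) next
        window <- L * 24 * 60                       # minutes in the occasion
        step <- window %/% n_ev
        if (step < 30) stop("too many events to space 30 min apart")
        onsets <- (seq_len(n_ev) - 1L) * step       # >= 30 min apart
        for (o in onsets) {
          base <- origin + ((t - 1L) * window + o) * 60
          n_photo <- sample(1:3, 1)
          offsets <- c(0, 7, 13)[seq_len(n_photo)]  # all < 30 min from onset
          for (off in offsets) {
            e <- e + 1L
            events[[e]] <- data.frame(camera_id = cam,
                                      timestamp = base + off * 60,
                                      species = species)
          }
        }
      }
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(camera_id = character(), timestamp = as.POSIXct(character()),
               species = character())
  list(events = events, deployments = do.call(rbind, deps))
}

#' Run the preparation pipeline on raw events
#'
#' Convenience wrapper chaining the independence filter, per-camera occasion
#' pooling and site aggregation.
#'
#' @param events photo-event data frame.
#' @param deployments deployment data frame.
#' @param species focal species tag to keep.
#' @inheritParams pool_occasions
#' @return a [count_matrix()].
#' @export
prepare_counts <- function(events, deployments, species = "focal",
                           occasion_length_days = 3, n_occasions = 15,
                           min_gap_minutes = 30, include_partial = TRUE) {
  ev <- events[events$species == species, , drop = FALSE]
  ev <- filter_independent_events(ev, min_gap_minutes)
  rows <- lapply(seq_len(nrow(deployments)), function(j) {
    dep <- deployments[j, , drop = FALSE]
    pool_occasions(ev[ev$camera_id == dep$camera_id, , drop = FALSE], dep,
                   occasion_length_days = occasion_length_days,
                   n_occasions = n_occasions,
                   include_partial = include_partial)
  })
  aggregate_to_sites(rows)
}
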