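# AIC multimodel ranking and parametric-bootstrap goodness of fit.
#
# Candidate models are ranked by ascending AIC; inference is restricted to
# models within 2 AIC units of the best.  Fit adequacy is judged by a
# parametric bootstrap: simulate data from the fitted model, refit, and
# compare the observed fit statistic with its bootstrap distribution.  The
# ratio of observed statistic to bootstrap mean is the overdispersion
# parameter c-hat, used (when > 1) to inflate standard errors.

#' Rank fitted models by AIC
#'
#' Builds the standard model-selection table: number of parameters, AIC,
#' difference from the best model (dAIC), Akaike weights and their running
#' sum, sorted ascending by AIC.  Rows with dAIC <= 2 are flagged as the
#' set inference should be drawn from.
#'
#' @param fits list of `nmix_fit` objects (named, or labels are taken from
#'   each spec).
#' @return data frame of class `aic_table` with columns `model`, `nPars`,
#'   `AIC`, `dAIC`, `AICwt`, `cumltvWt`, `in_delta2`.
#' @export
rank_models <- function(fits) {
  if (!length(fits)) stop("no fitted models supplied")
  if (inherits(fits, "nmix_fit")) fits <- list(fits)
  labels <- names(fits)
  if (is.null(labels))
    labels <- vapply(fits, function(f) f$spec$label, character(1))
  if (anyDuplicated(labels)) stop("model labels must be unique")
  conv <- vapply(fits, `[[`, logical(1), "converged")
  if (!any(conv)) stop("no converged fits to rank")
  if (any(!conv))
    warning("dropping non-converged fit(s): ",
            paste(labels[!conv], collapse = ", "))
  fits <- fits[conv]; labels <- labels[conv]

  aic <- vapply(fits, `[[`, numeric(1), "aic")
  npars <- vapply(fits, `[[`, integer(1), "n_params")
  ord <- order(aic)
  aic <- aic[ord]; npars <- npars[ord]; labels <- labels[ord]
  d <- aic - aic[1]
  w <- exp(-d / 2); w <- w / sum(w)
  structure(data.frame(model = labels, nPars = npars, AIC = aic, dAIC = d,
                       AICwt = w, cumltvWt = cumsum(w), in_delta2 = d <= 2,
                       row.names = NULL),
            class = c("aic_table", "data.frame"))
}

#' @export
print.aic_table <- function(x, digits = 3, ...) {
  cat("Model selection (ascending AIC; dAIC <= 2 marked *)\n")
  y <- as.data.frame(x)
  y$model <- paste0(ifelse(y$in_delta2, "* ", "  "), y$model)
  y$in_delta2 <- NULL
  print(y, digits = digits, row.names = FALSE)
  invisible(x)
}

# expected cell counts under the fitted model: E[y_it] = lambda_i * p_it,
# times (1 - psi) for the ZIP mixture (NB mean is lambda itself)
fitted_expected <- function(fit) {
  lam <- fit$fitted_lambda
  if (fit$spec$mixture == "ZIP")
    lam <- lam * (1 - plogis(fit$coefficients[["logit(psi)"]]))
  lam * fit$fitted_p
}

gof_statistics <- c("chisq", "sse", "freeman-tukey")

compute_gof_stat <- function(y, expected, statistic) {
  obs <- !is.na(y)
  yv <- y[obs]; ev <- expected[obs]
  switch(statistic,
         chisq = sum((yv - ev)^2 / ev),
         sse = sum((yv - ev)^2),
         `freeman-tukey` = sum((sqrt(yv) - sqrt(ev))^2))
}

# simulate one dataset from a fitted model, keeping design and missingness
simulate_from_fit <- function(fit) {
  y <- as_count_mat(fit$counts)
  R <- nrow(y); J <- ncol(y)
  lam <- fit$fitted_lambda
  spec <- fit$spec
  N <- switch(spec$mixture,
    P = rpois(R, lam),
    NB = rnbinom(R, size = exp(fit$coefficients[["log(alpha)"]]), mu = lam),
    ZIP = ifelse(runif(R) < plogis(fit$coefficients[["logit(psi)"]]),
                 0L, rpois(R, lam)),
    stop("parametric bootstrap supports the P/NB/ZIP mixtures"))
  ynew <- matrix(NA_integer_, R, J, dimnames = dimnames(y))
  for (i in seq_len(R)) {
    obs <- which(!is.na(y[i, ]))
    ynew[i, obs] <- rbinom(length(obs), size = N[i], prob = fit$fitted_p[i, obs])
  }
  cm <- fit$counts
  cm$counts <- ynew
  cm
}

#' Parametric-bootstrap goodness of fit and overdispersion
#'
#' Computes an observed fit statistic (Pearson chi-square on cell-wise
#' expected counts `lambda_i * p_it` by default), then repeatedly simulates
#' data from the fitted model (same design and missingness pattern), refits
#' the same specification (starting from the original MLE) and recomputes
#' the statistic.  The bootstrap p-value is the proportion of simulated
#' statistics at or above the observed one, and
#' `c_hat = observed / mean(bootstrap)` measures overdispersion.
#'
#' @param fit a converged `nmix_fit` (P/NB/ZIP mixtures).
#' @param n_boot bootstrap iterations (1000 for final inference; smaller
#'   values are fine for calibration studies).
#' @param seed integer seed; recorded in the result.
#' @param statistic `"chisq"` (default), `"sse"` or `"freeman-tukey"`.
#' @return object of class `gof_result`: `statistic_name`, `observed`,
#'   `bootstrap_stats`, `p_value`, `c_hat`, `n_fail`, `seed`.
#' @export
gof_bootstrap <- function(fit, n_boot = 1000, seed = NULL,
                          statistic = c("chisq", "sse", "freeman-tukey")) {
  statistic <- match.arg(statistic)
  if (!fit$converged) stop("goodness of fit requires a converged fit")
  if (!is.null(seed)) set.seed(seed)
  observed <- compute_gof_stat(as_count_mat(fit$counts), fitted_expected(fit),
                               statistic)
  boot <- rep(NA_real_, n_boot)
  n_fail <- 0L
  for (b in seq_len(n_boot)) {
    sim <- simulate_from_fit(fit)
    ref <- tryCatch(
      fit_nmix(fit$spec, sim, fit$covs, K = fit$K,
               start = unname(fit$coefficients), screen = FALSE,
               check_K = FALSE, hessian = FALSE),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(ref) || !ref$converged) { n_fail <- n_fail + 1L; next }
    boot[b] <- compute_gof_stat(as_count_mat(sim), fitted_expected(ref),
                                statistic)
  }
  if (n_fail > 0.1 * n_boot)
    warning(n_fail, " of ", n_boot, " bootstrap refits failed")
  ok <- boot[!is.na(boot)]
  structure(list(statistic_name = statistic, observed = observed,
                 bootstrap_stats = boot, p_value = mean(ok >= observed),
                 c_hat = observed / mean(ok), n_boot = n_boot,
                 n_fail = n_fail, seed = seed),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat("Parametric-bootstrap goodness of fit (", x$statistic_name, ")\n",
      sep = "")
  cat(sprintf("  observed %.3f, bootstrap mean %.3f over %d iterations (%d failed)\n",
              x$observed, mean(x$bootstrap_stats, na.rm = TRUE), x$n_boot,
              x$n_fail))
  cat(sprintf("  p-value %.3f, c-hat %.3f%s\n", x$p_value, x$c_hat,
              if (!is.null(x$seed)) paste0("  [seed ", x$seed, "]") else ""))
  invisible(x)
}

#' Goodness-of-fit sensitivity across fit statistics
#'
#' Because the choice of bootstrap fit statistic is a convention, this runs
#' [gof_bootstrap()] under all three provided statistics and tabulates
#' p-values and c-hat side by side.
#'
#' @inheritParams gof_bootstrap
#' @export
gof_sensitivity <- function(fit, n_boot = 200, seed = NULL) {
  res <- lapply(gof_statistics, function(s)
    gof_bootstrap(fit, n_boot = n_boot, seed = seed, statistic = s))
  data.frame(statistic = gof_statistics,
             observed = vapply(res, `[[`, numeric(1), "observed"),
             p_value = vapply(res, `[[`, numeric(1), "p_value"),
             c_hat = vapply(res, `[[`, numeric(1), "c_hat"))
}

#' Inflate a standard error for overdispersion
#'
#' Quasi-likelihood correction: multiply by `sqrt(c_hat)`, flooring `c_hat`
#' at 1 so that apparent under-dispersion never shrinks uncertainty.
#'
#' @param se positive standard error.
#' @param c_hat overdispersion ratio.
#' @export
c_hat_inflate <- function(se, c_hat) {
  stopifnot(se > 0)
  se * sqrt(max(c_hat, 1))
}

#' Per-site mean Pearson residuals
#'
#' Cell residuals `(y_it - E[y_it]) / sd(y_it)` under the fitted model's
#' marginal cell distribution, averaged within sites.  The marginal cell
#' variance follows from the law of total variance: `p(1-p) E[N] + p^2
#' Var(N)` with the mixture's `Var(N)`.  Intended for export and mapping;
#' judging spatial pattern is left to the analyst.
#'
#' @param fit a converged `nmix_fit`.
#' @return data frame with `site_id`, `mean_resid`, `n_cells`.
#' @export
residual_map <- function(fit) {
  y <- as_count_mat(fit$counts)
  lam <- fit$fitted_lambda
  spec <- fit$spec
  varN <- switch(spec$mixture,
    P = lam,
    NB = lam + lam^2 / exp(fit$coefficients[["log(alpha)"]]),
    ZIP = {
      psi <- plogis(fit$coefficients[["logit(psi)"]])
      (1 - psi) * lam * (1 + psi * lam)
    },
    stop("residuals are defined for the P/NB/ZIP mixtures"))
  EN <- if (spec$mixture == "ZIP")
    (1 - plogis(fit$coefficients[["logit(psi)"]])) * lam else lam
  p <- fit$fitted_p
  mu <- EN * p
  v <- p * (1 - p) * EN + p^2 * varN
  r <- (y - mu) / sqrt(v)
  data.frame(site_id = fit$counts$site_ids,
             mean_resid = rowMeans(r, na.rm = TRUE),
             n_cells = rowSums(!is.na(y)))
}
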