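# Independent brute-force oracles and small fixture builders.
# The oracles work in direct probability space with plain sums, deliberately
# sharing no code with the package's log-space implementations.

brute_site_loglik <- function(y, lambda, p, K, mixture = "P", alpha = NULL,
                              psi = NULL) {
  obs <- !is.na(y)
  y <- y[obs]
  p <- rep_len(p, length(obs))[obs]
  total <- 0
  for (N in max(y):K) {
    f <- switch(mixture,
                P = dpois(N, lambda),
                NB = dnbinom(N, size = alpha, mu = lambda),
                ZIP = psi * (N == 0) + (1 - psi) * dpois(N, lambda))
    total <- total + prod(dbinom(y, N, p)) * f
  }
  log(total)
}

brute_rn_loglik <- function(w, lambda, r, K) {
  w <- w[!is.na(w)]
  total <- 0
  for (N in 0:K) {
    q <- (1 - r)^N
    total <- total + prod(ifelse(w == 1, 1 - q, q)) * dpois(N, lambda)
  }
  log(total)
}

brute_posterior <- function(y, lambda, p, K, mixture = "P", alpha = NULL,
                            psi = NULL) {
  obs <- !is.na(y)
  y <- y[obs]
  p <- rep_len(p, length(obs))[obs]
  ns <- max(y):K
  un <- vapply(ns, function(N) {
    f <- switch(mixture,
                P = dpois(N, lambda),
                NB = dnbinom(N, size = alpha, mu = lambda),
                ZIP = psi * (N == 0) + (1 - psi) * dpois(N, lambda))
    prod(dbinom(y, N, p)) * f
  }, numeric(1))
  list(n = ns, post = un / sum(un))
}

# small standardized covariate table
tiny_covs <- function(n = 12, k = 2, seed = 99) {
  set.seed(seed)
  df <- data.frame(site_id = sprintf("S%02d", seq_len(n)))
  for (j in seq_len(k)) df[[paste0("x", j)]] <- rnorm(n)
  standardize_covariates(site_covariates(df))
}

# small count matrix simulated from a Poisson N-mixture
tiny_counts <- function(n = 12, Tocc = 5, lambda = 3, p = 0.3, seed = 99) {
  set.seed(seed + 1)
  N <- rpois(n, lambda)
  m <- t(vapply(N, function(Ni) rbinom(Tocc, Ni, p), integer(Tocc)))
  rownames(m) <- sprintf("S%02d", seq_len(n))
  count_matrix(m, n_occasions = Tocc)
}

# photo-event stream at one camera, at the given minute offsets
minute_events <- function(minutes, camera = "C1", species = "focal",
                          origin = as.POSIXct("2016-12-01 06:00:00",
                                              tz = "UTC")) {
  data.frame(camera_id = rep(camera, length(minutes)),
             timestamp = origin + minutes * 60,
             species = rep(species, length(minutes)))
}

one_deployment <- function(camera = "C1", site = "S01",
                           start = "2016-12-01", days = 45) {
  data.frame(camera_id = camera, site_id = site,
             active_start = as.Date(start),
             active_end = as.Date(start) + days - 1, trap_nights = days)
}
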