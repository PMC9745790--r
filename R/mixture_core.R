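# Likelihood engine for site-structured abundance models.
#
# The binomial N-mixture model treats the latent abundance N_i of site i as a
# draw from a count mixture (Poisson, negative binomial or zero-inflated
# Poisson) and the observed counts y_it as binomial thinnings of N_i with
# detection probability p_it.  N_i is never observed, so the likelihood sums
# it out over N = max(y_i) .. K.  Everything here is computed in log space:
# detection probabilities of a few percent make direct products underflow.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

MIXTURES <- c("P", "NB", "ZIP")

mixture_code <- function(mixture) {
  match(match.arg(mixture, MIXTURES), MIXTURES) - 1L
}

#' Probability mass of the latent-abundance mixture
#'
#' Evaluates the site-abundance distribution at integer abundances `N`.
#' Three mixtures are supported: Poisson with mean `lambda`; negative
#' binomial parameterized by mean `lambda` and dispersion `alpha`, so that
#' the variance is `lambda + lambda^2 / alpha`; and zero-inflated Poisson,
#' which puts probability `psi` on a structural zero and `1 - psi` on a
#' Poisson draw.
#'
#' @param N vector of non-negative integers.
#' @param lambda positive mean abundance.
#' @param mixture one of `"P"`, `"NB"`, `"ZIP"`.
#' @param alpha positive NB dispersion (required for `"NB"`).
#' @param psi zero-inflation probability in `[0, 1]` (required for `"ZIP"`).
#' @param log if `TRUE` return log probabilities.
#' @return numeric vector of (log) probabilities, one per element of `N`.
#' @examples
#' abundance_pmf(0:5, lambda = 2.6)
#' abundance_pmf(0, lambda = 2.6, mixture = "ZIP", psi = 0.3)
#' @export
abundance_pmf <- function(N, lambda, mixture = c("P", "NB", "ZIP"),
                          alpha = NULL, psi = NULL, log = FALSE) {
  mixture <- match.arg(mixture)
  if (any(N < 0) || any(N != round(N)))
    stop("N must contain non-negative integers")
  if (!is.finite(lambda) || lambda <= 0)
    stop("lambda must be a positive number")
  out <- switch(mixture,
    P = dpois(N, lambda, log = log),
    NB = {
      if (is.null(alpha) || !is.finite(alpha) || alpha <= 0)
        stop("NB mixture requires a positive dispersion 'alpha'")
      dnbinom(N, size = alpha, mu = lambda, log = log)
    },
    ZIP = {
      if (is.null(psi) || psi < 0 || psi > 1)
        stop("ZIP mixture requires 'psi' in [0, 1]")
      pr <- (1 - psi) * dpois(N, lambda) + psi * (N == 0)
      if (log) base::log(pr) else pr
    }
  )
  out
}

#' Truncation mass left above the latent-abundance bound K
#'
#' The marginal likelihood truncates the infinite sum over latent abundance
#' at `K`; this reports the prior mass `1 - sum_{N=0}^{K} f(N)` ignored by
#' that truncation, which should be negligible (< 1e-8) at a well-chosen `K`.
#'
#' @inheritParams abundance_pmf
#' @param K truncation bound.
#' @export
truncation_mass <- function(lambda, K, mixture = c("P", "NB", "ZIP"),
                            alpha = NULL, psi = NULL) {
  mixture <- match.arg(mixture)
  max(0, 1 - sum(abundance_pmf(0:K, lambda, mixture, alpha = alpha, psi = psi)))
}

#' Marginal log-likelihood of one site's counts
#'
#' Sums the latent abundance out of the joint likelihood of a single site:
#' `log sum_{N=max(y)}^{K} prod_t Binomial(y_t; N, p_t) * f(N)`, where `f`
#' is the abundance mixture.  Missing occasions (`NA` in `y`) contribute
#' nothing.  This is the plain-R reference implementation; the model fitter
#' uses a compiled equivalent, and the two are required to agree.
#'
#' @param y integer vector of counts for one site, `NA` for missing cells.
#' @param lambda positive mean abundance of the site.
#' @param p detection probability, scalar or one value per occasion.
#' @param mixture,alpha,psi see [abundance_pmf()].
#' @param K truncation bound; must be at least `max(y, na.rm = TRUE)`.
#' @return the site log-likelihood (scalar).
#' @export
site_marginal_loglik <- function(y, lambda, p, mixture = c("P", "NB", "ZIP"),
                                 alpha = NULL, psi = NULL, K = NULL) {
  mixture <- match.arg(mixture)
  obs <- !is.na(y)
  if (!any(obs)) stop("all occasions are missing for this site")
  y <- y[obs]
  p <- rep_len(p, length(obs))[obs]
  if (any(y < 0) || any(y != round(y))) stop("counts must be non-negative integers")
  if (any(p < 0 | p > 1)) stop("detection probabilities must lie in [0, 1]")
  if (is.null(K)) K <- max(y) + 100L
  if (K < max(y)) stop("truncation bound K = ", K, " is below max(y) = ", max(y))

  Ns <- max(y):K
  ll <- vapply(Ns, function(N) {
    abundance_pmf(N, lambda, mixture, alpha = alpha, psi = psi, log = TRUE) +
      sum(dbinom(y, size = N, prob = p, log = TRUE))
  }, numeric(1))
  logsumexp(ll)
}

#' Marginal log-likelihood of one site under the Royle-Nichols model
#'
#' The Royle-Nichols model links detection/non-detection data to abundance
#' through per-individual detectability: `P(w_t = 1 | N) = 1 - (1 - r)^N`
#' with `N ~ Poisson(lambda)`.  Heterogeneity in site abundance therefore
#' induces heterogeneity in detection.
#'
#' @param w binary vector (0/1, `NA` for missing) for one site.
#' @param lambda positive mean site abundance.
#' @param r per-individual detection probability in `[0, 1]`.
#' @param K truncation bound for the Poisson sum (from 0, unlike the
#'   N-mixture case: `w` does not bound `N` from below).
#' @export
rn_site_loglik <- function(w, lambda, r, K = NULL) {
  obs <- !is.na(w)
  if (!any(obs)) stop("all occasions are missing for this site")
  w <- w[obs]
  if (!all(w %in% c(0, 1))) stop("Royle-Nichols data must be binary")
  if (r < 0 || r > 1) stop("r must lie in [0, 1]")
  if (is.null(K)) K <- ceiling(lambda + 10 * sqrt(lambda)) + 50L

  ll <- vapply(0:K, function(N) {
    q <- (1 - r)^N
    dpois(N, lambda, log = TRUE) +
      sum(ifelse(w == 1, log(1 - q), N * log(1 - r)))
  }, numeric(1))
  logsumexp(ll)
}

# --- full-data negative log-likelihoods ------------------------------------

# unpack a packed coefficient vector
# order: [beta (ps) | alpha (pd) | log(nb dispersion) or logit(psi)]
unpack_theta <- function(theta, ps, pd, mixture) {
  n_aux <- as.integer(mixture %in% c("NB", "ZIP"))
  if (length(theta) != ps + pd + n_aux)
    stop("theta has length ", length(theta), "; expected ", ps + pd + n_aux)
  list(beta = theta[seq_len(ps)],
       alpha = theta[ps + seq_len(pd)],
       aux = if (n_aux) theta[ps + pd + 1] else 0)
}

#' Negative log-likelihood of the full N-mixture data set
#'
#' Evaluates `-sum_i site_marginal_loglik` with `lambda_i = exp(X_state beta)`
#' (log link) and `p_it = plogis(X_det alpha)` (logit link).  `theta` packs
#' the coefficients as `[beta | alpha | log(dispersion) or logit(psi)]`; the
#' auxiliary slot is present only for the NB / ZIP mixtures.
#'
#' @param theta packed coefficient vector.
#' @param counts a [count_matrix()] or a plain site-by-occasion integer
#'   matrix with `NA` for missing cells.
#' @param X_state abundance design matrix, one row per site, including an
#'   intercept column.
#' @param X_det detection design matrix with one row per site-by-column cell
#'   (site-major: rows `(i-1)*J + 1 .. i*J` belong to site `i`), including an
#'   intercept column.
#' @param mixture one of `"P"`, `"NB"`, `"ZIP"`.
#' @param K truncation bound; defaults to `max(counts) + 100`.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference).
#' @return the scalar negative log-likelihood.
#' @export
nmix_negloglik <- function(theta, counts, X_state, X_det,
                           mixture = c("P", "NB", "ZIP"), K = NULL,
                           engine = c("cpp", "r")) {
  mixture <- match.arg(mixture)
  engine <- match.arg(engine)
  y <- as_count_mat(counts)
  R <- nrow(y); J <- ncol(y)
  if (nrow(X_state) != R) stop("X_state must have one row per site")
  if (nrow(X_det) != R * J)
    stop("X_det must have R * J = ", R * J, " rows (site-major cell order)")
  if (is.null(K)) K <- default_K(y)
  th <- unpack_theta(theta, ncol(X_state), ncol(X_det), mixture)

  if (engine == "cpp") {
    return(.nmix_negloglik_cpp(y, as.matrix(X_state), as.matrix(X_det),
                               th$beta, th$alpha, mixture_code(mixture),
                               th$aux, as.integer(K)))
  }

  lambda <- exp(pmin(as.vector(as.matrix(X_state) %*% th$beta), 500))
  p <- plogis(as.vector(as.matrix(X_det) %*% th$alpha))
  nb_alpha <- if (mixture == "NB") exp(min(th$aux, 500)) else NULL
  psi <- if (mixture == "ZIP") plogis(th$aux) else NULL
  total <- 0
  for (i in seq_len(R)) {
    total <- total + site_marginal_loglik(
      y[i, ], lambda[i], p[(i - 1) * J + seq_len(J)],
      mixture = mixture, alpha = nb_alpha, psi = psi, K = K)
  }
  if (!is.finite(total)) return(1e10)
  -total
}

#' Negative log-likelihood of the Royle-Nichols model
#'
#' As [nmix_negloglik()] but on binarized detection data, with
#' `lambda_i = exp(X_state beta)` and per-individual detection
#' `r_it = plogis(X_det alpha)`.
#'
#' @inheritParams nmix_negloglik
#' @param w binary site-by-occasion matrix (or a [count_matrix()], which is
#'   binarized first).
#' @export
rn_negloglik <- function(theta, w, X_state, X_det, K = NULL,
                         engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  wmat <- as_count_mat(w)
  if (any(wmat > 1L, na.rm = TRUE)) wmat <- binarize(wmat)
  R <- nrow(wmat); J <- ncol(wmat)
  if (is.null(K)) K <- default_K(wmat)
  th <- unpack_theta(theta, ncol(X_state), ncol(X_det), "P")

  if (engine == "cpp") {
    return(.rn_negloglik_cpp(wmat, as.matrix(X_state), as.matrix(X_det),
                             th$beta, th$alpha, as.integer(K)))
  }
  lambda <- exp(pmin(as.vector(as.matrix(X_state) %*% th$beta), 500))
  r <- plogis(as.vector(as.matrix(X_det) %*% th$alpha))
  total <- 0
  for (i in seq_len(R)) {
    ri <- r[(i - 1) * J + seq_len(J)]
    obs <- !is.na(wmat[i, ])
    total <- total + rn_site_loglik(wmat[i, obs], lambda[i], ri[obs][1], K = K)
  }
  if (!is.finite(total)) return(1e10)
  -total
}

#' Reduce counts to detection/non-detection
#'
#' Maps every present cell to 1 if the count is positive and 0 otherwise;
#' missing cells stay missing.  This is the data reduction the
#' Royle-Nichols model operates on.
#'
#' @param counts a [count_matrix()] or integer matrix.
#' @return an object of the same shape with cells in \{0, 1, NA\}.
#' @export
binarize <- function(counts) {
  if (inherits(counts, "count_matrix")) {
    counts$counts <- binarize(counts$counts)
    return(counts)
  }
  out <- counts
  out[!is.na(out)] <- as.integer(out[!is.na(out)] > 0)
  out
}

# default latent-count truncation bound: max observed count + 100
default_K <- function(y) {
  max(y, na.rm = TRUE) + 100L
}

# coerce count_matrix / data.frame / matrix to an integer matrix
as_count_mat <- function(counts) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  m <- as.matrix(counts)
  storage.mode(m) <- "integer"
  m
}
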