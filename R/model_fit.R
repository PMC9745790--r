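# Maximum-likelihood fitting of N-mixture and Royle-Nichols models.
#
# Coefficients live on link scales: log for mean abundance lambda, logit for
# detection probability p (per-individual r in the RN case), log for the NB
# dispersion and logit for the ZIP zero-inflation probability.  Fits start
# from all-zero coefficients (a deterministic, reproducible start), are
# optimized by BFGS, and report Wald standard errors from the inverse of the
# numerically evaluated observed information.

#' Specify an abundance model
#'
#' Names the abundance mixture and the covariates entering the two linear
#' predictors: `log(lambda_i) = beta_0 + X beta` for site abundance and
#' `logit(p_it) = alpha_0 + X alpha` for detection.  An empty covariate list
#' is the constant "(.)" model.  Mixture `"RN"` is the Royle-Nichols model
#' fitted to binarized counts.
#'
#' @param lambda character vector of abundance covariate names (may be empty).
#' @param p character vector of detection covariate names (may be empty).
#' @param mixture one of `"P"`, `"NB"`, `"ZIP"`, `"RN"`.
#' @param K optional latent-abundance truncation bound override.
#' @param label optional display label; default is built from the formula.
#' @return an object of class `nmix_spec`.
#' @examples
#' nmix_spec(lambda = c("mixed", "human_CR"), p = "fruit_density")
#' parse_model_label("p(fruit_density)lambda(mixed+human_CR)")
#' @export
nmix_spec <- function(lambda = character(), p = character(),
                      mixture = c("P", "NB", "ZIP", "RN"), K = NULL,
                      label = NULL) {
  mixture <- match.arg(mixture)
  lambda <- as.character(lambda); p <- as.character(p)
  if (is.null(label))
    label <- paste0("p(", if (length(p)) paste(p, collapse = "+") else ".",
                    ")lambda(",
                    if (length(lambda)) paste(lambda, collapse = "+") else ".",
                    ")", if (mixture != "P") paste0("[", mixture, "]"))
  structure(list(lambda = lambda, p = p, mixture = mixture, K = K,
                 label = label), class = "nmix_spec")
}

#' Parse a compact model label
#'
#' Accepts the `"p(a+b)lambda(c+d)"` syntax used in model-selection tables;
#' `"."` (or empty parentheses) denotes the constant model.
#'
#' @param label model label string.
#' @param mixture abundance mixture for the resulting spec.
#' @inheritParams nmix_spec
#' @return an `nmix_spec`.
#' @export
parse_model_label <- function(label, mixture = c("P", "NB", "ZIP", "RN"),
                              K = NULL) {
  mixture <- match.arg(mixture)
  m <- regmatches(label, regexec("p\\(([^)]*)\\).*?lambda\\(([^)]*)\\)", label))[[1]]
  if (length(m) != 3)
    stop("cannot parse model label '", label,
         "'; expected p(...)lambda(...) syntax")
  split_terms <- function(s) {
    s <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    s[s != "" & s != "."]
  }
  nmix_spec(lambda = split_terms(m[3]), p = split_terms(m[2]),
            mixture = mixture, K = K)
}

build_design <- function(covs, vars, n_sites) {
  X <- matrix(1, n_sites, 1, dimnames = list(NULL, "(Intercept)"))
  if (length(vars)) {
    missing <- setdiff(vars, covariate_names(covs))
    if (length(missing))
      stop("unknown covariate(s): ", paste(missing, collapse = ", "))
    X <- cbind(X, as.matrix(covs[vars]))
  }
  X
}

theta_names <- function(spec, Xs, Xd) {
  nm <- c(paste0("lam(", colnames(Xs), ")"), paste0("p(", colnames(Xd), ")"))
  if (spec$mixture == "NB") nm <- c(nm, "log(alpha)")
  if (spec$mixture == "ZIP") nm <- c(nm, "logit(psi)")
  nm
}

#' Fit an N-mixture or Royle-Nichols model by maximum likelihood
#'
#' Maximizes the marginal likelihood (latent site abundances summed out up
#' to `K`) by BFGS from an all-zero start.  Standard errors come from the
#' inverse of the numerically evaluated observed information; per-coefficient
#' two-sided Wald P-values are reported.  Formulas containing a covariate
#' pair flagged by the collinearity screen (|r| >= 0.7) are refused.
#'
#' @param spec an [nmix_spec()] (or a label string parsed by
#'   [parse_model_label()]).
#' @param counts a [count_matrix()].
#' @param covs a standardized [site_covariates()] table (standardize first
#'   with [standardize_covariates()]); may be omitted for constant models.
#' @param K truncation bound; default `max(counts) + 100` with a
#'   convergence check (doubling `K` must not move the log-likelihood).
#' @param start optional start values (packed coefficient vector).
#' @param screen logical: apply the collinearity screen (default TRUE).
#' @param check_K verify truncation convergence at the MLE (default TRUE).
#' @param hessian compute the observed information for standard errors
#'   (default TRUE; bootstrap refits that only need point estimates turn
#'   this off).
#' @return an object of class `nmix_fit` with components `coefficients`,
#'   `se`, `p_values`, `vcov`, `loglik`, `n_params`, `aic`, `converged`,
#'   `fitted_lambda`, `fitted_p`, and the inputs needed for downstream
#'   goodness-of-fit work.
#' @export
fit_nmix <- function(spec, counts, covs = NULL, K = NULL, start = NULL,
                     screen = TRUE, check_K = TRUE, hessian = TRUE) {
  if (is.character(spec)) spec <- parse_model_label(spec)
  stopifnot(inherits(spec, "nmix_spec"), inherits(counts, "count_matrix"))
  y <- as_count_mat(counts)
  R <- nrow(y); J <- ncol(y)
  used <- union(spec$lambda, spec$p)
  if (length(used)) {
    if (is.null(covs)) stop("spec uses covariates but none were supplied")
    if (!is_standardized(covs))
      stop("covariates must be Z-standardized before fitting; ",
           "see standardize_covariates()")
    if (!identical(as.character(covs$site_id), as.character(counts$site_ids)))
      stop("covariate site_id order does not match the count matrix")
    if (screen && length(covariate_names(covs)) >= 2 && nrow(covs) >= 3) {
      flagged <- collinearity_screen(covs)
      for (k in seq_len(nrow(flagged))) {
        pair <- c(flagged$var1[k], flagged$var2[k])
        if (all(pair %in% spec$lambda) || all(pair %in% spec$p))
          stop("covariates '", pair[1], "' and '", pair[2],
               "' are strongly correlated (|r| = ",
               round(abs(flagged$r[k]), 2),
               " >= 0.7) and cannot enter the same formula")
      }
    }
  }

  Xs <- build_design(covs, spec$lambda, R)
  Xd_site <- build_design(covs, spec$p, R)
  Xd <- Xd_site[rep(seq_len(R), each = J), , drop = FALSE]  # site-major cells
  is_rn <- spec$mixture == "RN"
  if (is.null(K)) K <- if (is.null(spec$K)) default_K(y) else spec$K

  nll <- if (is_rn) {
    w <- as_count_mat(binarize(counts))
    function(th) .rn_negloglik_cpp(w, Xs, Xd, th[seq_len(ncol(Xs))],
                                   th[ncol(Xs) + seq_len(ncol(Xd))],
                                   as.integer(K))
  } else {
    mixc <- mixture_code(spec$mixture)
    n_aux <- as.integer(spec$mixture %in% c("NB", "ZIP"))
    function(th) {
      aux <- if (n_aux) th[length(th)] else 0
      .nmix_negloglik_cpp(y, Xs, Xd, th[seq_len(ncol(Xs))],
                          th[ncol(Xs) + seq_len(ncol(Xd))], mixc, aux,
                          as.integer(K))
    }
  }

  npar <- ncol(Xs) + ncol(Xd) +
    as.integer(spec$mixture %in% c("NB", "ZIP"))
  if (is.null(start)) start <- numeric(npar)
  if (length(start) != npar)
    stop("start has length ", length(start), "; expected ", npar)

  opt <- optim(start, nll, method = "BFGS", hessian = hessian,
               control = list(maxit = 1000, reltol = 1e-8))
  converged <- opt$convergence == 0L

  nm <- theta_names(spec, Xs, Xd)
  est <- setNames(opt$par, nm)
  vc <- if (hessian)
    tryCatch(solve(opt$hessian), error = function(e) NULL) else NULL
  if (hessian && (is.null(vc) || any(!is.finite(vc)) || any(diag(vc) < 0))) {
    warning("observed information is singular or not positive definite; ",
            "standard errors are undefined")
    vc <- NULL
  }
  if (is.null(vc)) vc <- matrix(NA_real_, npar, npar)
  dimnames(vc) <- list(nm, nm)
  se <- sqrt(diag(vc))
  z <- est / se
  pval <- 2 * pnorm(-abs(z))

  beta <- est[seq_len(ncol(Xs))]
  alpha <- est[ncol(Xs) + seq_len(ncol(Xd))]
  fitted_lambda <- as.vector(exp(Xs %*% beta))
  fitted_p <- matrix(plogis(Xd %*% alpha), R, J, byrow = TRUE)
  dimnames(fitted_p) <- dimnames(y)
  fitted_p[is.na(y)] <- NA_real_

  loglik <- -opt$value
  if (check_K && !is_rn) {
    nb_alpha <- if (spec$mixture == "NB") exp(est[["log(alpha)"]]) else NULL
    psi <- if (spec$mixture == "ZIP") plogis(est[["logit(psi)"]]) else NULL
    tm <- max(vapply(fitted_lambda, truncation_mass, numeric(1), K = K,
                     mixture = spec$mixture, alpha = nb_alpha, psi = psi))
    if (tm > 1e-8)
      warning(sprintf(paste0("latent-abundance truncation at K = %d leaves ",
                             "prior mass %.2e unaccounted; increase K"), K, tm))
  }

  structure(list(spec = spec, coefficients = est, se = se, p_values = pval,
                 vcov = vc, loglik = loglik, n_params = npar,
                 aic = -2 * loglik + 2 * npar, converged = converged,
                 fitted_lambda = fitted_lambda, fitted_p = fitted_p,
                 K = K, counts = counts, covs = covs,
                 optim = opt[c("convergence", "counts", "message")]),
            class = "nmix_fit")
}

#' @export
print.nmix_fit <- function(x, ...) {
  cat("N-mixture model fit:", x$spec$label, "\n")
  cat(sprintf("  mixture %s, %d sites, K = %d, logLik = %.3f, AIC = %.2f%s\n",
              x$spec$mixture, length(x$fitted_lambda), x$K, x$loglik, x$aic,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(coef_table(x), digits = 3)
  invisible(x)
}

#' @export
coef.nmix_fit <- function(object, ...) object$coefficients

#' @export
vcov.nmix_fit <- function(object, ...) object$vcov

#' @export
logLik.nmix_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = nrow(object$counts$counts),
            class = "logLik")
}

#' Link-scale coefficient table
#'
#' One row per coefficient: estimate, standard error and two-sided Wald
#' P-value, the layout used in published N-mixture coefficient tables.
#'
#' @param fit an `nmix_fit`.
#' @export
coef_table <- function(fit) {
  data.frame(parameter = names(fit$coefficients),
             estimate = unname(fit$coefficients), se = unname(fit$se),
             p_value = unname(fit$p_values), row.names = NULL)
}

#' Write a coefficient table to CSV
#' @param fit an `nmix_fit`.
#' @param path output file.
#' @export
write_coef_table <- function(fit, path) {
  write.csv(coef_table(fit), path, row.names = FALSE)
  invisible(path)
}

# --- derived quantities ----------------------------------------------------

fit_intercept <- function(fit, which = c("lam", "p")) {
  which <- match.arg(which)
  nm <- paste0(which, "((Intercept))")
  if (!nm %in% names(fit$coefficients)) stop("fit has no ", which, " intercept")
  nm
}

#' Mean site abundance with delta-method uncertainty
#'
#' With Z-standardized covariates the abundance intercept is the log mean
#' abundance at average covariate values, so `lambda_hat = exp(beta_0)`.
#' The SE is `lambda_hat * se(beta_0)` (delta method) and the 95% CI is
#' normal on the log scale, back-transformed.  If an overdispersion ratio
#' `c_hat > 1` is supplied the intercept SE is first inflated by
#' `sqrt(c_hat)`.
#'
#' @param fit an `nmix_fit`.
#' @param c_hat optional overdispersion ratio from [gof_bootstrap()].
#' @return list with `estimate`, `se`, `ci` (length-2 vector).
#' @export
mean_site_abundance <- function(fit, c_hat = NULL) {
  if (!fit$converged) warning("fit did not converge; estimates are suspect")
  nm <- fit_intercept(fit, "lam")
  b0 <- fit$coefficients[[nm]]
  s0 <- fit$se[[nm]]
  if (!is.null(c_hat)) s0 <- c_hat_inflate(s0, c_hat)
  lam <- exp(b0)
  list(estimate = lam, se = lam * s0,
       ci = exp(b0 + c(-1, 1) * qnorm(0.975) * s0))
}

#' Detection probability at average covariates
#'
#' `p_hat = plogis(alpha_0)` with delta-method SE
#' `p_hat * (1 - p_hat) * se(alpha_0)`.  For the Royle-Nichols model this is
#' the per-individual detection probability r.
#'
#' @param fit an `nmix_fit`.
#' @return list with `estimate` and `se`.
#' @export
detection_estimate <- function(fit) {
  nm <- fit_intercept(fit, "p")
  a0 <- fit$coefficients[[nm]]
  s0 <- fit$se[[nm]]
  p <- plogis(a0)
  list(estimate = p, se = p * (1 - p) * s0)
}

#' Empirical-Bayes site-level abundance
#'
#' Conditional on the data and the MLE, the posterior of each latent site
#' abundance is `P(N_i = n | y_i) \propto prod_t Binomial(y_it; n, p_it) *
#' f(n)` over `n = max(y_i) .. K`.  Returns the posterior mode (the value
#' mapped in site-abundance maps) and mean per site.
#'
#' @param fit a converged `nmix_fit` (N-mixture mixtures or RN).
#' @return data frame with `site_id`, `mode`, `mean`.
#' @export
eb_site_abundance <- function(fit) {
  y <- as_count_mat(fit$counts)
  R <- nrow(y)
  spec <- fit$spec
  nb_alpha <- if (spec$mixture == "NB")
    exp(fit$coefficients[["log(alpha)"]]) else NULL
  psi <- if (spec$mixture == "ZIP")
    plogis(fit$coefficients[["logit(psi)"]]) else NULL
  is_rn <- spec$mixture == "RN"
  if (is_rn) y <- as_count_mat(binarize(fit$counts))

  out <- data.frame(site_id = fit$counts$site_ids, mode = NA_integer_,
                    mean = NA_real_)
  for (i in seq_len(R)) {
    obs <- which(!is.na(y[i, ]))
    yi <- y[i, obs]
    pi <- fit$fitted_p[i, obs]
    lo <- if (is_rn) 0L else max(yi)
    ns <- lo:fit$K
    lp <- if (is_rn) {
      q <- outer(ns, pi, function(n, r) (1 - r)^n)
      rowSums(log(ifelse(rep(yi == 1, each = length(ns)), 1 - q, q))) +
        dpois(ns, fit$fitted_lambda[i], log = TRUE)
    } else {
      vapply(ns, function(n) sum(dbinom(yi, n, pi, log = TRUE)), numeric(1)) +
        abundance_pmf(ns, fit$fitted_lambda[i],
                      mixture = if (is_rn) "P" else spec$mixture,
                      alpha = nb_alpha, psi = psi, log = TRUE)
    }
    post <- exp(lp - logsumexp(lp))
    out$mode[i] <- ns[which.max(post)]
    out$mean[i] <- sum(ns * post)
  }
  out
}

#' Predicted abundance along one covariate
#'
#' Sweeps one standardized abundance covariate over a grid with all other
#' covariates held at their mean (0 on the standardized scale):
#' `lambda(x) = exp(beta_0 + beta_cov * x)`, with a delta-method CI on the
#' linear predictor, back-transformed.
#'
#' @param fit an `nmix_fit`.
#' @param covariate name of a covariate in the abundance formula.
#' @param grid standardized covariate values (default -2..2).
#' @param level CI level, default 0.95.
#' @return data frame with `x`, `lambda`, `lower`, `upper`.
#' @export
response_curve <- function(fit, covariate, grid = seq(-2, 2, length.out = 50),
                           level = 0.95) {
  nm0 <- fit_intercept(fit, "lam")
  nmc <- paste0("lam(", covariate, ")")
  if (!nmc %in% names(fit$coefficients))
    stop("covariate '", covariate, "' is not in the abundance formula")
  b0 <- fit$coefficients[[nm0]]; bc <- fit$coefficients[[nmc]]
  v <- fit$vcov[c(nm0, nmc), c(nm0, nmc)]
  eta <- b0 + bc * grid
  se <- sqrt(v[1, 1] + grid^2 * v[2, 2] + 2 * grid * v[1, 2])
  zq <- qnorm(1 - (1 - level) / 2)
  data.frame(x = grid, lambda = exp(eta), lower = exp(eta - zq * se),
             upper = exp(eta + zq * se))
}
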