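# Maximum-likelihood fitting, Wald inference and derived quantities.

make_fake_fit <- function(b0, se0, a0 = 0, sea = 0) {
  nm <- c("lam((Intercept))", "p((Intercept))")
  vc <- diag(c(se0^2, sea^2))
  dimnames(vc) <- list(nm, nm)
  structure(list(spec = nmix_spec(), coefficients = setNames(c(b0, a0), nm),
                 se = setNames(c(se0, sea), nm), vcov = vc, converged = TRUE),
            class = "nmix_fit")
}

test_that("model labels parse to specs and back", {
  sp <- parse_model_label("p(fruit_density)lambda(sal.forest+vildist+human_CR+mixed)")
  expect_equal(sp$p, "fruit_density")
  expect_equal(sp$lambda, c("sal.forest", "vildist", "human_CR", "mixed"))
  null <- parse_model_label("p(.)lambda(.)", mixture = "ZIP")
  expect_equal(length(null$lambda), 0)
  expect_equal(null$mixture, "ZIP")
  expect_error(parse_model_label("lambda(x)"), "cannot parse")
})

test_that("parameter counts match the formula and the AIC identity is exact", {
  cnt <- tiny_counts()
  covs <- tiny_covs()
  specs <- list(P_null = nmix_spec(mixture = "P"),
                NB_null = nmix_spec(mixture = "NB"),
                ZIP_null = nmix_spec(mixture = "ZIP"),
                P_top = nmix_spec(lambda = c("x1", "x2"), p = "x1"),
                NB_top = nmix_spec(lambda = c("x1", "x2"), p = "x1",
                                   mixture = "NB"),
                ZIP_top = nmix_spec(lambda = c("x1", "x2"), p = "x1",
                                    mixture = "ZIP"))
  want <- c(2L, 3L, 3L, 5L, 6L, 6L)
  for (i in seq_along(specs)) {
    f <- suppressWarnings(fit_nmix(specs[[i]], cnt, covs))
    expect_equal(f$n_params, want[i], info = names(specs)[i])
    expect_identical(f$aic, -2 * f$loglik + 2 * f$n_params)
    expect_equal(length(f$coefficients), f$n_params)
  }
  # with an intercept plus 4 abundance and 1 detection covariate the count
  # is 7 for Poisson and 8 for NB/ZIP, as in published N-mixture tables
  covs4 <- tiny_covs(k = 4)
  f7 <- suppressWarnings(
    fit_nmix(nmix_spec(lambda = paste0("x", 1:4), p = "x1"), cnt, covs4))
  expect_equal(f7$n_params, 7L)
  f8 <- suppressWarnings(
    fit_nmix(nmix_spec(lambda = paste0("x", 1:4), p = "x1",
             mixture = "ZIP"), cnt, covs4))
  expect_equal(f8$n_params, 8L)
})

test_that("the MLE beats the zero start and random perturbations", {
  cnt <- tiny_counts(n = 20)
  covs <- tiny_covs(n = 20)
  spec <- nmix_spec(lambda = "x1", p = "x2")
  fit <- fit_nmix(spec, cnt, covs)
  y <- as.matrix(cnt)
  R <- nrow(y); J <- ncol(y)
  Xs <- cbind(1, covs$x1)
  Xd <- cbind(1, rep(covs$x2, each = J))
  nll <- function(th) nmix_negloglik(th, cnt, Xs, Xd, "P", K = 40)
  at_mle <- nll(unname(coef(fit)))
  expect_lte(at_mle, nll(numeric(4)) + 1e-6)
  set.seed(77)
  for (i in 1:100) {
    th <- unname(coef(fit)) + rnorm(4, sd = 0.3)
    expect_lte(at_mle, nll(th) + 1e-6)
  }
})

test_that("simulated Poisson data at a large design recovers the truth", {
  set.seed(101)
  cfg <- sim_config(n_sites = 400, replicates = 1,
                    state_coefs = c("(Intercept)" = 0.95),
                    det_coefs = c("(Intercept)" = qlogis(0.08)))
  cv <- simulate_covariates(cfg)
  cnt <- simulate_counts(cfg, cv$standardized)
  fit <- fit_nmix(nmix_spec(), cnt)
  # truth within ~2 Wald SEs of the estimate at this sample size
  expect_lt(abs(coef(fit)[["lam((Intercept))"]] - 0.95),
            2.5 * fit$se[["lam((Intercept))"]] + 0.05)
  expect_lt(abs(coef(fit)[["p((Intercept))"]] - qlogis(0.08)),
            2.5 * fit$se[["p((Intercept))"]] + 0.05)
  expect_true(fit$converged)
  # Wald p-values are two-sided normal tail probabilities
  z <- coef(fit) / fit$se
  expect_equal(unname(fit$p_values), unname(2 * pnorm(-abs(z))))
})

test_that("collinear covariate pairs are refused in one formula", {
  set.seed(13)
  x <- rnorm(30)
  covs <- standardize_covariates(site_covariates(data.frame(
    site_id = sprintf("S%02d", 1:30), a = x,
    b = 0.95 * x + rnorm(30, sd = 0.05), c = rnorm(30))))
  cnt <- tiny_counts(n = 30)
  expect_error(fit_nmix(nmix_spec(lambda = c("a", "b")), cnt, covs),
               "strongly correlated")
  expect_s3_class(fit_nmix(nmix_spec(lambda = c("a", "c")), cnt, covs),
                  "nmix_fit")
})

test_that("unstandardized covariates are rejected before fitting", {
  covs <- site_covariates(data.frame(site_id = sprintf("S%02d", 1:12),
                                     x1 = rnorm(12, 50, 10)))
  expect_error(fit_nmix(nmix_spec(lambda = "x1"), tiny_counts(), covs),
               "standardized")
})

test_that("mean site abundance applies the log-link delta method", {
  # identity at beta_0 = 0 with no uncertainty
  f <- make_fake_fit(0, 0)
  expect_equal(mean_site_abundance(f),
               list(estimate = 1, se = 0, ci = c(1, 1)))
  # printed-coefficient arithmetic: exp(0.95) = 2.586, SE 2.586 * 0.25
  f <- make_fake_fit(0.95, 0.25)
  lam <- mean_site_abundance(f)
  expect_equal(lam$estimate, exp(0.95), tolerance = 1e-12)
  expect_equal(lam$se, exp(0.95) * 0.25)
  expect_equal(lam$ci, exp(0.95 + c(-1, 1) * qnorm(0.975) * 0.25))
  # c-hat inflates the SE before back-transforming
  infl <- mean_site_abundance(f, c_hat = 1.31)
  expect_equal(infl$se, exp(0.95) * 0.25 * sqrt(1.31))
  # the log-normal CI convention: 1.62 with se 0.34 gives roughly 1.08-2.44
  rn <- make_fake_fit(log(1.62), 0.34 / 1.62)
  expect_equal(mean_site_abundance(rn)$ci, c(1.08, 2.44), tolerance = 0.01)
})

test_that("detection estimate applies the logit-link delta method", {
  f <- make_fake_fit(0, 0, a0 = 0, sea = 0)
  expect_equal(detection_estimate(f), list(estimate = 0.5, se = 0))
  f <- make_fake_fit(0, 0, a0 = qlogis(0.08), sea = 0.15)
  d <- detection_estimate(f)
  expect_equal(d$estimate, 0.08)
  expect_equal(d$se, 0.08 * 0.92 * 0.15)
})

test_that("empirical-Bayes site abundance matches brute-force posteriors", {
  cnt <- tiny_counts(n = 15, lambda = 2.5, p = 0.25)
  fit <- fit_nmix(nmix_spec(), cnt, K = 60)
  eb <- eb_site_abundance(fit)
  lam <- fit$fitted_lambda[1]
  for (i in c(1, 7, 15)) {
    o <- brute_posterior(as.matrix(cnt)[i, ], lam, fit$fitted_p[i, 1],
                         K = fit$K)
    expect_equal(eb$mean[i], sum(o$n * o$post), tolerance = 1e-12)
    expect_equal(eb$mode[i], o$n[which.max(o$post)])
  }
  # an all-zero site under small lambda and decent detection sits at mode 0
  m <- rbind(matrix(0L, 5, 3), c(2L, 2L, 2L))
  rownames(m) <- c(paste0("z", 1:5), "nz")
  f2 <- fit_nmix(nmix_spec(), count_matrix(m, 3), K = 60)
  eb2 <- eb_site_abundance(f2)
  expect_equal(eb2$mode[eb2$site_id == "z1"], 0L)
  expect_gte(eb2$mode[eb2$site_id == "nz"], 2L)
})

test_that("response curves respect the centering identity and monotonicity", {
  cnt <- tiny_counts(n = 25)
  covs <- tiny_covs(n = 25)
  fit <- suppressWarnings(fit_nmix(nmix_spec(lambda = "x1"), cnt, covs))
  rc <- response_curve(fit, "x1", grid = c(-1, 0, 1))
  b0 <- coef(fit)[["lam((Intercept))"]]
  bc <- coef(fit)[["lam(x1)"]]
  expect_equal(rc$lambda[rc$x == 0], exp(b0))
  expect_equal(rc$lambda[rc$x == 0], mean_site_abundance(fit)$estimate)
  expect_equal(rc$lambda[rc$x == 1], exp(b0 + bc))
  if (bc > 0) expect_true(all(diff(rc$lambda) > 0))
  expect_true(all(rc$lower <= rc$lambda & rc$lambda <= rc$upper))
  expect_error(response_curve(fit, "nope"), "not in the abundance formula")
})

test_that("Royle-Nichols and N-mixture nulls give compatible lambda at low p", {
  set.seed(55)
  cfg <- sim_config(n_sites = 150, replicates = 1,
                    state_coefs = c("(Intercept)" = log(2)),
                    det_coefs = c("(Intercept)" = qlogis(0.1)))
  cv <- simulate_covariates(cfg)
  cnt <- simulate_counts(cfg, cv$standardized)
  nmix <- fit_nmix(nmix_spec(), cnt)
  rn <- fit_nmix(nmix_spec(mixture = "RN"), cnt)
  ci_n <- mean_site_abundance(nmix)$ci
  ci_r <- mean_site_abundance(rn)$ci
  expect_true(ci_n[1] <= ci_r[2] && ci_r[1] <= ci_n[2]) # overlapping CIs
})
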