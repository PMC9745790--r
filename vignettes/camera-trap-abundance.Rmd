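---
title: "Estimating relative abundance from camera-trap counts with N-mixture models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating relative abundance from camera-trap counts with N-mixture models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmixcam)
```

## The problem

Camera traps photograph animals that cannot be told apart individually, so
classical capture–recapture is unavailable. For an elusive, unmarked species
the practical question is *relative* abundance: how many individuals use
each surveyed site, and which habitat or disturbance gradients drive the
variation. `nmixcam` implements the repeated-count route to that question:
binomial N-mixture models fitted to a site × occasion matrix of independent
photographic detections, together with the data-preparation conventions the
camera-trap literature uses to build that matrix.

## The model

Latent abundance at site $i$ follows a count mixture and the observed count
$y_{it}$ at occasion (and spatial replicate) $t$ is a binomial thinning of
it:

$$N_i \sim f(\cdot\,;\lambda_i), \qquad
  y_{it} \mid N_i \sim \mathrm{Binomial}(N_i, p_{it}),$$

with log and logit links carrying covariates:
$\log \lambda_i = \beta_0 + \mathbf{x}_i^\top\boldsymbol\beta$ and
$\mathrm{logit}\, p_{it} = \alpha_0 + \mathbf{w}_{it}^\top\boldsymbol\alpha$.
Three abundance mixtures $f$ are supported:

* **Poisson** with mean $\lambda_i$;
* **negative binomial** parameterized by mean $\lambda$ and dispersion
  $\alpha$, variance $\lambda + \lambda^2/\alpha$ (the convention of the
  established N-mixture software family, required for comparability of the
  dispersion estimate);
* **zero-inflated Poisson**, a structural-zero probability $\psi$ mixed
  with a Poisson, with $\psi$ a scalar on the logit scale — covariates act
  only on $\lambda$ and $p$, mirroring standard practice.

Because $N_i$ is never observed the likelihood marginalizes it:

$$L_i = \sum_{N=\max_t y_{it}}^{K}
   \Big[\prod_{t\,\text{observed}} \binom{N}{y_{it}} p_{it}^{y_{it}}
        (1-p_{it})^{N-y_{it}}\Big] f(N;\lambda_i).$$

The lower limit exploits the binomial support exactly; the upper limit $K$
truncates an infinite sum. The companion Royle–Nichols model works on
detection/non-detection data with $P(w_{it}=1\mid N_i)=1-(1-r)^{N_i}$ and a
Poisson prior, and is used here as a null-model cross-check on
$\hat\lambda$.

When sites hold several cameras, their occasion histories enter as parallel
*spatial replicate* columns of the same site — extra binomial looks at the
same latent $N_i$ — rather than being summed, which would change the
observation model.

With all covariates Z-standardized, $\exp(\beta_0)$ is the mean site
abundance at average covariate values and $\mathrm{plogis}(\alpha_0)$ the
detection probability per replicate-occasion; both are reported with
delta-method standard errors, and confidence intervals for $\lambda$ are
normal on the log scale and back-transformed (so always positive).

### Relative, not absolute

Wide-ranging animals violate the closure assumption: the same bear can use
several 12.4 km² grid cells within a six-week survey. Estimates are
therefore read as the number of individuals *using* a site during the
survey, which is why the package speaks of relative abundance throughout.

## Numerical choices

* All likelihood sums run in log space with log-sum-exp; detection
  probabilities near 0.05 make direct products underflow at 15+ occasions.
* The compiled (C++) objective and a plain-R reference implementation are
  both exported; the test suite holds them to each other and to brute-force
  enumeration oracles at $10^{-10}$.
* Truncation default $K = \max y + 100$. This is generous for Poisson-like
  posteriors; `fit_nmix()` re-checks at the MLE that the prior mass above
  $K$ is below $10^{-8}$ and warns otherwise (heavy-tailed NB fits on tiny
  data sets do trip this check, intentionally). Doubling $K$ moves the
  log-likelihood by less than $10^{-6}$ in the tested regimes.
* Optimization is BFGS from an all-zero coefficient start — deterministic,
  so headline fits are exactly reproducible — with a relative objective
  tolerance of $10^{-8}$. Standard errors come from the inverse of the
  numerically evaluated observed information; a singular information matrix
  yields `NA` standard errors with a warning, never silence.
* Wald inference throughout (two-sided normal P-values), matching how
  N-mixture coefficient tables are conventionally reported; no profile
  likelihood.
* ZIP mean site abundance is reported as $\exp(\beta_0)$ with $\hat\psi$
  alongside; the $(1-\psi)$-weighted variant is a one-line computation left
  to the user because published tables report the unweighted one.

## Data preparation rules

* **Independence filter:** photographs of the same species at the same
  camera count as one event unless separated by ≥ 30 minutes *from the
  last retained event*. Measuring from the last retained event (not the
  last photograph) guarantees all retained events are pairwise ≥ 30 min
  apart — the strictest reading of the rule — and makes filtering
  idempotent. The boundary is inclusive.
* **Occasion pooling:** events are binned into 3-day occasions (15 by
  default) anchored at each camera's own activation date, because
  deployments are typically staggered. Occasions wholly outside the active
  period are missing; partially covered occasions are kept but flagged,
  with a toggle to drop them instead (both conventions exist in the
  literature and the choice is not recoverable from a deposited matrix).
* **Aggregation:** cameras map to sites as sorted replicate blocks
  (`rep1_occ1..rep1_occT, rep2_occ1, ...`); sites with fewer cameras carry
  missing cells, which the likelihood skips. Missing is always distinct
  from zero.
* **Covariate QC:** Z-standardization uses the sample (n−1) SD; original
  centers and scales are retained so response curves can be drawn in
  natural units. Pairs with $|r| \ge 0.7$ are flagged and refused within a
  single formula.

## Model selection and goodness of fit

`rank_models()` builds the usual AIC table (ΔAIC, Akaike weights,
cumulative weights) and marks the ΔAIC ≤ 2 set from which inference should
be drawn. `gof_bootstrap()` runs a parametric bootstrap: simulate from the
fitted model on the same design and missingness pattern, refit, and compare
fit statistics. The default statistic is the Pearson χ² on cell-wise
expected counts $\hat\lambda_i \hat p_{it}$ (times $1-\hat\psi$ under ZIP);
because the statistic is a convention rather than part of the model,
sum-of-squared-errors and Freeman–Tukey variants are provided and
`gof_sensitivity()` tabulates all three. Overdispersion is summarized by
$\hat c$ = observed / bootstrap mean; standard errors are inflated by
$\sqrt{\hat c}$ with $\hat c$ floored at 1, the usual quasi-likelihood
practice — apparent under-dispersion never tightens intervals. Bootstrap
refits start from the original MLE (speed, and basin consistency); every
result records its seed. A single seeded RNG stream drives each bootstrap,
which keeps results bit-reproducible for a given seed and iteration count.

`eb_site_abundance()` gives the empirical-Bayes posterior of each $N_i$ at
the MLE — the site-level map quantity — as mode and mean;
`residual_map()` exports per-site mean Pearson residuals (under the
marginal cell variance implied by the mixture) for spatial inspection,
deliberately without any automated spatial-pattern test: that judgment is
left to the analyst.

## The synthetic-survey generator

`sim_config()` defaults encode the survey design this package was built
around: 73 grid-cell sites carrying 1–4 camera replicates (143 cameras in
total, allocated deterministically), 15 occasions of 3 days, mean site
abundance $\exp(0.95) \approx 2.6$ with standardized effects 0.33 / 0.27 /
0.25 / 0.21 of mixed-forest area, human capture rate, village distance and
sal-forest area, and detection $p = 0.08$ with a 0.27 effect of
fruiting-tree density. NB dispersion defaults to $\alpha = 1$ and ZIP
zero-inflation to $\psi = 0.3$, roughly the fraction of unoccupied sites
such surveys report. Covariates are drawn multivariate-normal on natural
scales comparable to the field ranges (e.g., human capture rate mean 2.2,
SD 2.6) and then Z-standardized.

`simulate_counts()` draws $N_i$ and thins binomially, returning the latent
truth for recovery tests. `simulate_photo_events()` goes one layer deeper:
every counted detection becomes a cluster of 1–3 photographs within < 30
minutes, with cluster onsets ≥ 30 minutes apart inside the correct
occasion window, so the preparation pipeline must reproduce the generating
count matrix *exactly* — an end-to-end identity the tests assert.

What the generator does **not** emulate: spatial autocorrelation among
sites, animal movement between sites (the closure violation is only
reflected in interpretation, not simulated), serial dependence of
detections across occasions, camera failures mid-occasion, and non-normal
covariate shapes (real covariate distributions are skewed and bounded).
Passing tests therefore demonstrate that the estimator recovers the world
it assumes, not that real surveys satisfy those assumptions.

## Validation scales used by the test suite

The automated checks run at sizes chosen to finish in minutes on one core
while keeping Monte-Carlo error well inside the asserted tolerances: 200
replicate surveys at the 73-site design for coefficient bias (< 0.1) and
95% Wald coverage (within 0.90–0.99); bootstrap-GoF calibration with 40
replicate surveys at 60 bootstrap iterations plus one 200-iteration run at
200 sites; and 30 replicates of NB-generated data for the overdispersion
check. Final-inference GoF runs use 1,000 iterations, as
`reproduce_study()` does when deposited data are supplied.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
cfg <- sim_config()
cv  <- simulate_covariates(cfg)
cnt <- simulate_counts(cfg, cv$standardized)

fit <- fit_nmix("p(fruit_density)lambda(mixed+human_CR+vildist+sal.forest)",
                cnt, cv$standardized)
fit
mean_site_abundance(fit)
detection_estimate(fit)

null <- fit_nmix(nmix_spec(), cnt)
rank_models(list(fit, null))

g <- gof_bootstrap(fit, n_boot = 200, seed = 1)
mean_site_abundance(fit, c_hat = g$c_hat)
head(eb_site_abundance(fit))
```

## Known limitations

* Abundance estimates from N-mixture models are sensitive to the mixture
  choice when detection is low; the NB mixture in particular can win on AIC
  while implying implausibly large abundance. The package deliberately
  reports all mixtures side by side rather than auto-selecting.
* Detection covariates are site-level in the current design-matrix builder
  (occasion-varying detection covariates are not yet exposed, though the
  likelihood core accepts cell-level designs).
* No model averaging, no Bayesian fitting, no spatially explicit
  (density) estimators — the model family here is the site-structured
  count likelihood and its standard companions.
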