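# nmixcam

Binomial N-mixture models for estimating the relative abundance of unmarked
species from camera-trap count data.

Camera traps yield repeated counts of animals that cannot be identified
individually, so capture–recapture is off the table. For wildlife managers
working with elusive, conflict-prone species — the motivating case is a
sloth-bear survey across 73 forest grid cells — the question is how many
individuals *use* each site and which environmental and anthropogenic
gradients drive that variation. `nmixcam` answers it with the
site-structured count likelihood:

    N_i  ~ f(lambda_i)                     (latent site abundance)
    y_it | N_i ~ Binomial(N_i, p_it)       (imperfect detection)

    log(lambda_i) = beta_0 + x_i' beta     logit(p_it) = alpha_0 + w_it' alpha

where `f` is Poisson, negative binomial (mean `lambda`, variance
`lambda + lambda^2/alpha`) or zero-inflated Poisson, and the latent `N_i`
is summed out of the likelihood up to a truncation bound `K`. The
Royle–Nichols model (`P(w=1|N) = 1-(1-r)^N`) is included as a
detection/non-detection cross-check on `lambda`. Around that core the
package covers the full workflow:

* **Data preparation** — thin photographs to independent events (≥ 30 min
  rule), pool them into 3-day sampling occasions anchored per camera,
  stack 1–4 cameras per site as spatial replicates, Z-standardize
  covariates and screen collinear pairs (|r| ≥ 0.7).
* **Fitting and inference** — maximum likelihood (compiled objective,
  BFGS, deterministic start), Wald SEs/P-values, mean site abundance
  `exp(beta_0)` and detection `plogis(alpha_0)` with delta-method
  uncertainty, covariate response curves, empirical-Bayes site-level
  abundance for mapping.
* **Selection and adequacy** — AIC tables with Akaike weights and the
  ΔAIC ≤ 2 reporting rule; parametric-bootstrap goodness of fit with
  overdispersion ratio ĉ and `sqrt(ĉ)` SE inflation (floored at 1).
* **Synthetic surveys** — a generator that reproduces the study design
  (73 sites, 143 cameras, 15 occasions, p ≈ 0.08, mean abundance ≈ 2.6)
  down to raw clustered photo events, so the whole pipeline is testable
  end to end without any data download.

## A worked example

Simulate a survey at the default (study-shaped) truth, fit the generating
model, and check adequacy:

```r
library(nmixcam)
set.seed(1)
cfg <- sim_config()
cv  <- simulate_covariates(cfg)
cnt <- simulate_counts(cfg, cv$standardized)

fit <- fit_nmix("p(fruit_density)lambda(mixed+human_CR+vildist+sal.forest)",
                cnt, cv$standardized)
fit
#> N-mixture model fit: p(fruit_density)lambda(mixed+human_CR+vildist+sal.forest)
#>   mixture P, 73 sites, K = 103, logLik = -1212.390, AIC = 2438.78
#>          parameter estimate     se  p_value
#> 1 lam((Intercept))   0.9570 0.2062 3.48e-06
#> 2       lam(mixed)   0.3621 0.0862 2.67e-05
#> 3    lam(human_CR)   0.2660 0.0827 1.30e-03
#> 4     lam(vildist)   0.0152 0.0906 8.67e-01
#> 5  lam(sal.forest)   0.1682 0.0896 6.06e-02
#> 6   p((Intercept))  -2.4371 0.2132 3.00e-30
#> 7 p(fruit_density)   0.2272 0.0818 5.48e-03

unlist(mean_site_abundance(fit))
#>  estimate        se       ci1       ci2
#> 2.6038585 0.5370343 1.7380443 3.9009818
unlist(detection_estimate(fit))
#>   estimate         se
#> 0.08038959 0.01576397

g <- gof_bootstrap(fit, n_boot = 100, seed = 1)
g
#> Parametric-bootstrap goodness of fit (chisq)
#>   observed 2162.660, bootstrap mean 2128.411 over 100 iterations (0 failed)
#>   p-value 0.330, c-hat 1.016  [seed 1]
```

The generating truth was `beta_0 = 0.95` (so mean site abundance
`exp(0.95) = 2.59`) and `p = 0.08`: the fit returns 2.60 ± 0.54 and
0.080 ± 0.016, the covariate effects land near their generating values
(0.33 / 0.27 / 0.25 / 0.21, within sampling noise at 73 sites), and the
bootstrap finds no lack of fit on correctly specified data (ĉ ≈ 1.02).
With a ĉ above 1, `mean_site_abundance(fit, c_hat = g$c_hat)` widens the
interval by `sqrt(ĉ)`.

`reproduce_study(counts_csv, covs_csv)` runs the complete published-style
ladder (detection screening, per-mixture nulls and top models, RN null,
AIC tables, optional 1,000-iteration GoF) on a deposited detection matrix
and covariate table.

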