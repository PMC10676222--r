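# mvarmi

A missing-data workbench for multilevel intensive longitudinal data.

Intensive longitudinal designs — ecological momentary assessment (EMA)
prompts in smoking-cessation studies, daily-diary protocols, ambulatory
monitoring — produce many short, noisy time series nested within persons,
and they are never complete: prompts are missed, items skipped, lapses
reported late. The standard dynamic model for such data is the multilevel
bivariate VAR(1),

    y1[i,t] − μ1[i] = ar1·(y1[i,t−1] − μ1[i]) + cr1·(y2[i,t−1] − μ2[i])
                      + c1·x1[i,t] + d1·x2[i,t] + ζ1[i,t]
    y2[i,t] − μ2[i] = ar2·(y2[i,t−1] − μ2[i]) + cr2·(y1[i,t−1] − μ1[i])
                      + c2·x1[i,t] + d2·x2[i,t] + ζ2[i,t]
    ζ[i,t] ~ N(0, Σ),    θ[i] = B·X[i] + ν[i],  ν[i] ~ N(0, Δ)

with person-specific baselines (and optionally person-specific AR/CR
coefficients) regressed on time-invariant covariates. The question the
package is built around: **what happens to this model's estimates when the
missing data are handled by single-level multiple imputation, multilevel
(random-intercept) multiple imputation, Bayesian full-information
estimation, or listwise deletion?**

`mvarmi` provides every stage as a tested, composable function:

- `simulate_panel()` — multi-subject panels at controlled ICC, with AR(1)
  time-varying covariates and a person-level covariate;
- `calibrate_intercept()` / `apply_mar()` — logistic missing-at-random
  amputation calibrated to a target rate (30% by default), DVs amputated
  jointly per occasion;
- `impute_panel()` — chained-equations multiple imputation with lagged
  predictors and auxiliaries, in single-level and multilevel
  (person-random-intercept) variants;
- `fit_mvar()` / `fit_mvar_bfiml()` / `listwise_prepare()` — a bespoke
  compiled Gibbs-within-slice sampler for the full posterior, with
  full-information data augmentation and a listwise-deletion baseline;
  `rhat()`, `ess()`, `summarize_draws()` for diagnostics;
- `pool_posterior()` / `pool_rubin()` / `mc_metrics()` / `run_study()` —
  pooling across imputations, bias / relative bias / RMSE / dSD metrics,
  and the full Monte Carlo comparison loop;
- `ema_prepare()` and friends — the EMA preprocessing pipeline (item
  scoring, lapse time-stamp adjustment, six-hour block aggregation,
  participant filtering, detrending, baseline coding), exercised on
  synthetic prompt streams from `synth_ema_stream()`.

A thin CLI (`exec/mvarmi`) exposes the stages as subcommands
(`simulate`, `amputate`, `impute`, `fit`, `study`, `ema-prep`, `run`).

## Worked example

Simulate a 50-person, 50-occasion panel at the default true values
(ar = 0.4/0.3, cr = −0.3/−0.2, covariate effects 0.3/0.3/−0.5/−0.4, unit
noise variances, noise covariance 0.3, ICC 0.5) and fit the model to the
complete data:

```r
library(mvarmi)
sp  <- mvar_spec()
pan <- simulate_panel(sim_design(N = 50, T_occasions = 50,
                                 icc_target = 0.5, seed = 3), sp)
fit <- fit_mvar(pan, sp, settings = mcmc_settings_study(seed = 11))
summarize_draws(fit)
#>            parameter   mean     sd ci_low ci_high  rhat  ess  flag
#> 7                ar1  0.394 0.0173  0.361   0.428 1.000 2431 FALSE
#> 8                ar2  0.281 0.0189  0.242   0.317 1.000 2256 FALSE
#> 9                cr1 -0.314 0.0184 -0.350  -0.278 0.999 2742 FALSE
#> 10               cr2 -0.191 0.0176 -0.224  -0.157 1.000 2547 FALSE
#> 15          sigma2_1  1.020 0.0299  0.962   1.079 0.999 2576 FALSE
#> 17               rho  0.308 0.0189  0.273   0.345 1.001 2449 FALSE
```

Posterior means sit on the generating values within a posterior SD or two;
`rhat` below 1.1 and `ess` above 300 mean the convergence gates pass.
Impose 30% MAR missingness and compare multilevel against single-level
imputation (m = 5 completed sets each, pooled by posterior mixing):

```r
psi0 <- calibrate_intercept(pan, slope = 0.5, target_rate = 0.30)
amp  <- apply_mar(pan, missingness_model(psi0, 0.5, psi0, 0.5), seed = 7)
cs   <- impute_panel(amp, imputation_config(m = 5, method = "multilevel",
                                            seed = 5))
fits <- lapply(cs$panels, fit_mvar, spec = sp,
               settings = mcmc_settings_study(seed = 13))
pool_posterior(fits)
```

The full comparison — complete-data fit, single-level MI, multilevel MI,
full-information estimation and listwise deletion over Monte Carlo
replications, with per-parameter and per-group bias / relative bias /
RMSE / dSD tables — is one call:

```r
res <- run_study(conditions = data.frame(N = 50, T_occasions = 50,
                                         icc_target = 0.5),
                 methods = c("complete", "slmi", "mlmi", "bfiml", "ld"),
                 H = 20, seed = 1)
res[[1]]$group_metrics
```

At this smoke scale the qualitative findings are already clear: the
single-level route over-estimates the process-noise variances and
under-estimates the random-intercept variances (large positive and negative
relative biases), the multilevel route stays much closer with smaller RMSE,
full-information estimation is nearly unbiased throughout, and listwise
deletion attenuates the AR/CR coefficients. The reference-scale comparison
(H = 100, N = T = 100) uses the same call.

## Layout

```
R/            model spec, panels, simulation, amputation, imputation,
              sampler front end, diagnostics, pooling/metrics, EMA, I/O
src/          the Gibbs-within-slice sampler (RcppArmadillo)
tests/        testthat suite (unit, property and acceptance checks)
scripts/      acceptance.R
vignettes/    methods vignette: model, algorithms, design choices
exec/         mvarmi CLI
```
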