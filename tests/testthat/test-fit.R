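test_that("the sampler matches the conjugate normal-inverse-gamma limit", {
  set.seed(101)
  Tn <- 60
  y1 <- rnorm(Tn, 1.5, 1)
  y2 <- rnorm(Tn, -0.5, sqrt(2))
  pan <- panel_data(data.frame(person_id = 1, t = 1:Tn, y1 = y1, y2 = y2,
                               x1 = 0, x2 = 0),
                    data.frame(person_id = 1))
  fit <- fit_mvar(pan, paper_spec(),
                  settings = mcmc_settings_study(seed = 7,
                                                 iterations = 4000,
                                                 burn_in = 500,
                                                 adaptation = 100),
                  estimate = list(arcr = FALSE, cd = FALSE, corr = FALSE,
                                  delta_zero = TRUE),
                  inits = list(ar = c(0, 0), cr = c(0, 0),
                               cd = c(0, 0, 0, 0), sigma = c(1, 1, 0)))
  s <- summarize_draws(fit)
  rownames(s) <- s$parameter
  for (dv in 1:2) {
    or <- grid_oracle(if (dv == 1) y1 else y2)
    mu_p <- paste0("b_mu", dv, "_(Intercept)")
    s2_p <- paste0("sigma2_", dv)
    mcse_mu <- s[mu_p, "sd"] / sqrt(s[mu_p, "ess"])
    mcse_s2 <- s[s2_p, "sd"] / sqrt(s[s2_p, "ess"])
    expect_lt(abs(s[mu_p, "mean"] - or$mu_mean), 3 * mcse_mu)
    expect_lt(abs(s[s2_p, "mean"] - or$s2_mean), 3 * mcse_s2)
    expect_equal(s[mu_p, "sd"], or$mu_sd, tolerance = 0.05)
    expect_equal(s[s2_p, "sd"], or$s2_sd, tolerance = 0.08)
  }
})

test_that("convergence diagnostics behave on known chains", {
  # identical constant chains: R-hat 1 by convention
  expect_equal(rhat(list(rep(2, 100), rep(2, 100))), 1.0)
  # chains at different constants: far above the 1.1 threshold
  expect_gt(rhat(list(rep(0, 100), rep(5, 100))), 10)
  # i.i.d. standard normal chains, 4 x 1000
  set.seed(103)
  ch <- replicate(4, rnorm(1000), simplify = FALSE)
  expect_lt(rhat(ch), 1.01)
  expect_gt(rhat(ch), 0.99)
  e <- ess(ch)
  expect_equal(e, 4000, tolerance = 0.15)
  # cross-check against coda on an autocorrelated chain
  set.seed(104)
  ar_ch <- lapply(1:2, function(i)
    as.numeric(arima.sim(list(ar = 0.7), 2000)))
  e_coda <- sum(sapply(ar_ch, function(v)
    coda::effectiveSize(coda::mcmc(v))))
  expect_equal(ess(ar_ch), e_coda, tolerance = 0.25)
  expect_error(rhat(list(rnorm(100))), "2 chains")
})

test_that("complete-data fit recovers the generating parameters", {
  pan <- sim_small(N = 40, Tn = 40, seed = 105)
  fit <- fit_mvar(pan, paper_spec(), settings = fast_settings(seed = 9))
  s <- summarize_draws(fit)
  rownames(s) <- s$parameter
  truth <- c(ar1 = 0.4, ar2 = 0.3, cr1 = -0.3, cr2 = -0.2,
             c1 = 0.3, c2 = 0.3, d1 = -0.5, d2 = -0.4,
             sigma2_1 = 1, sigma2_2 = 1, rho = 0.3)
  for (pn in names(truth)) {
    expect_lt(abs(s[pn, "mean"] - truth[pn]), 3.5 * s[pn, "sd"] + 0.02)
  }
  expect_true(all(s$rhat < 1.1))
})

test_that("posterior draws respect the prior supports", {
  pan <- sim_small(N = 15, Tn = 15, seed = 107)
  fit <- fit_mvar(pan, paper_spec(), settings = fast_settings(seed = 11))
  all_draws <- do.call(rbind, fit$draws)
  for (vp in c("sigma2_1", "sigma2_2", "delta2_mu1", "delta2_mu2")) {
    expect_true(all(all_draws[, vp] > 0))
    expect_true(all(all_draws[, vp] < 100))
  }
  expect_true(all(abs(all_draws[, "rho"]) < 1))
})

test_that("two seeds give consistent posteriors on the same data", {
  pan <- sim_small(N = 25, Tn = 25, seed = 109)
  f1 <- fit_mvar(pan, paper_spec(), settings = fast_settings(seed = 13))
  f2 <- fit_mvar(pan, paper_spec(), settings = fast_settings(seed = 14))
  s1 <- summarize_draws(f1); rownames(s1) <- s1$parameter
  s2 <- summarize_draws(f2); rownames(s2) <- s2$parameter
  for (pn in c("ar1", "ar2", "cr1", "cr2", "sigma2_1")) {
    mcse <- s1[pn, "sd"] / sqrt(s1[pn, "ess"]) +
      s2[pn, "sd"] / sqrt(s2[pn, "ess"])
    expect_lt(abs(s1[pn, "mean"] - s2[pn, "mean"]), 5 * mcse + 0.005)
  }
  expect_true(all(s1$rhat < 1.1))
})

test_that("full-information fit equals the complete-data fit when nothing
           is missing, and handles 30% MAR with small bias", {
  pan <- sim_small(N = 30, Tn = 30, seed = 111)
  fc <- fit_mvar(pan, paper_spec(), settings = fast_settings(seed = 15))
  fb <- fit_mvar_bfiml(pan, paper_spec(), settings = fast_settings(seed = 16))
  sc <- summarize_draws(fc); rownames(sc) <- sc$parameter
  sb <- summarize_draws(fb); rownames(sb) <- sb$parameter
  for (pn in c("ar1", "ar2", "cr1", "cr2", "sigma2_1", "sigma2_2")) {
    expect_lt(abs(sc[pn, "mean"] - sb[pn, "mean"]), 0.02)
    # overlapping 95% intervals
    expect_true(sc[pn, "ci_low"] < sb[pn, "ci_high"] &&
                  sb[pn, "ci_low"] < sc[pn, "ci_high"])
  }
  amp <- mar_panel(sim_small(N = 50, Tn = 50, seed = 112), seed = 30)
  fm <- fit_mvar_bfiml(amp, paper_spec(), settings = fast_settings(seed = 17))
  sm <- summarize_draws(fm); rownames(sm) <- sm$parameter
  truth <- c(ar1 = 0.4, ar2 = 0.3, cr1 = -0.3, cr2 = -0.2)
  for (pn in names(truth))
    expect_lt(abs(sm[pn, "mean"] - truth[pn]), 0.05)
})

test_that("an augmented missing cell sits between its neighbour-implied
           conditional predictions", {
  # two independent AR(1) processes (cr = 0, r = 0); the conditional mean of
  # a missing middle point is a convex combination of the forward
  # prediction a*y[t-1] and the backward prediction y[t+1]/a
  set.seed(113)
  a <- 0.8; Tn <- 30
  y1 <- numeric(Tn); y2 <- numeric(Tn)
  y1[1] <- rnorm(1); y2[1] <- rnorm(1)
  for (t in 2:Tn) {
    y1[t] <- a * y1[t - 1] + rnorm(1, 0, 0.5)
    y2[t] <- a * y2[t - 1] + rnorm(1, 0, 0.5)
  }
  tm <- 15
  rec <- data.frame(person_id = 1, t = 1:Tn, y1 = y1, y2 = y2,
                    x1 = 0, x2 = 0)
  rec$y1[tm] <- NA; rec$y2[tm] <- NA
  pan <- panel_data(rec, data.frame(person_id = 1))
  fit <- fit_mvar_bfiml(pan, paper_spec(),
                        settings = mcmc_settings_study(seed = 19,
                                                       iterations = 3000,
                                                       burn_in = 500,
                                                       adaptation = 100),
                        estimate = list(arcr = FALSE, cd = FALSE,
                                        sigma = FALSE, corr = FALSE,
                                        delta_zero = TRUE, between = FALSE),
                        inits = list(ar = c(a, a), cr = c(0, 0),
                                     cd = rep(0, 4), sigma = c(0.25, 0.25, 0),
                                     B = matrix(0, 2, 1)))
  for (dv in 1:2) {
    yy <- if (dv == 1) y1 else y2
    fwd <- a * yy[tm - 1]
    bwd <- yy[tm + 1] / a
    imp <- fit$ymean[tm, dv]
    expect_gt(imp, min(fwd, bwd) - 0.05)
    expect_lt(imp, max(fwd, bwd) + 0.05)
  }
})

test_that("listwise deletion re-links lags to the nearest earlier retained
           row and attenuation follows", {
  rec <- data.frame(person_id = 1, t = 1:5,
                    y1 = c(1, 2, NA, 4, 5), y2 = 1:5,
                    x1 = rnorm(5), x2 = rnorm(5))
  pan <- panel_data(rec, data.frame(person_id = 1))
  ld <- listwise_prepare(pan)
  expect_equal(ld$meta$original_t, c(1, 2, 4, 5))
  expect_equal(ld$records$t, 1:4)  # consecutive: pairs (1,2), (2,4), (4,5)

  # no missingness: identity on records
  full <- tiny_panel()
  expect_identical(listwise_prepare(full)$records, full$records)

  # persons reduced below 2 rows are dropped with a warning
  rec2 <- data.frame(person_id = rep(1:2, each = 3), t = rep(1:3, 2),
                     y1 = c(1, 2, 3, NA, NA, 6), y2 = 1,
                     x1 = 0.5, x2 = 0.5)
  expect_warning(listwise_prepare(panel_data(rec2,
                                             data.frame(person_id = 1:2))),
                 "dropped")
})

test_that("the random-VAR-parameter variant recovers person-averaged
           dynamics", {
  sp <- paper_spec(random_var_params = TRUE)
  sp$re_var[c("ar1", "ar2", "cr1", "cr2")] <- 0.005
  d <- sim_design(N = 40, T_occasions = 40, icc_target = 0.4, seed = 115)
  pan <- simulate_panel(d, sp)
  fit <- fit_mvar(pan, sp, settings = fast_settings(seed = 21))
  s <- summarize_draws(fit)
  rownames(s) <- s$parameter
  expect_lt(abs(s["b_ar1_(Intercept)", "mean"] - 0.4), 0.07)
  expect_lt(abs(s["b_ar2_(Intercept)", "mean"] - 0.3), 0.07)
  expect_lt(abs(s["b_cr1_(Intercept)", "mean"] + 0.3), 0.07)
  expect_lt(abs(s["b_cr2_(Intercept)", "mean"] + 0.2), 0.07)
  expect_true(all(s[c("delta2_ar1", "delta2_ar2"), "mean"] > 0))
})
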