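test_that("covariate generator follows its AR(1) law and is reproducible", {
  sp0 <- paper_spec(cov_gen = list(ar = c(0, 0), noise_var = c(1, 1),
                                   x3_sd = 1))
  d <- sim_design(N = 60, T_occasions = 200, icc_target = 0.5, seed = 21)
  cv <- simulate_covariates(d, sp0)
  x <- cv$x[cv$x$t >= 1, ]
  # lag-1 autocorrelation ~ 0 when the AR coefficient is 0
  ac <- cor(x$x1[-1][diff(x$t) == 1], x$x1[-nrow(x)][diff(x$t) == 1])
  expect_lt(abs(ac), 0.03)

  sp3 <- paper_spec()  # cov AR 0.3, noise var 1
  cv3 <- simulate_covariates(d, sp3)
  x3 <- cv3$x[cv3$x$t >= 1, ]
  expect_equal(var(x3$x1), 1 / (1 - 0.09), tolerance = 0.05)
  expect_equal(var(x3$x2), 1 / (1 - 0.09), tolerance = 0.05)

  cv_again <- simulate_covariates(d, sp3)
  expect_identical(cv3, cv_again)

  bad <- paper_spec(cov_gen = list(ar = c(1.1, 0), noise_var = c(1, 1),
                                   x3_sd = 1))
  expect_error(simulate_covariates(d, bad), "non-stationary")
})

test_that("random-intercept variance solves the ICC identity", {
  sp <- paper_spec()
  expect_equal(solve_re_variance_for_icc(sp, 0), c(0, 0))
  dm <- solve_re_variance_for_icc(sp, 0.5)
  vw <- dm  # at icc 0.5, Delta equals the within variance
  expect_equal(dm / (dm + vw), c(0.5, 0.5))
  expect_error(solve_re_variance_for_icc(sp, 1))
})

test_that("simulated panels realise the designed ICC empirically", {
  # slope on x3 set to 0 so all between-person variance is the random
  # intercept; one-way decomposition of person means vs within
  B <- matrix(c(2, 0, 2, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("mu1", "mu2"), c("(Intercept)", "x3")))
  sp <- paper_spec(between_B = B)
  d <- sim_design(N = 400, T_occasions = 100, icc_target = 0.5, seed = 31)
  pan <- simulate_panel(d, sp)
  rec <- pan$records
  half <- rec$t <= max(rec$t) / 2
  for (dv in c("y1", "y2")) {
    # the covariance of first-half and second-half person means is an
    # (essentially) unbiased estimate of the random-intercept variance:
    # within-person noise is nearly independent across the two halves
    pm1 <- tapply(rec[[dv]][half], rec$person_id[half], mean)
    pm2 <- tapply(rec[[dv]][!half], rec$person_id[!half], mean)
    between <- cov(pm1, pm2)
    within <- mean(tapply(rec[[dv]], rec$person_id, var))
    icc_emp <- between / (between + within)
    expect_equal(icc_emp, 0.5, tolerance = 0.03)
  }
})

test_that("panel recursion has the model's stationary moments", {
  # degenerate case: no dynamics, no covariate effects, no random effects
  B <- matrix(c(1.5, 0, -0.5, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("mu1", "mu2"), c("(Intercept)", "x3")))
  sp0 <- paper_spec(ar = c(0, 0), cr = c(0, 0),
                    cov_effects = c(c1 = 0, c2 = 0, d1 = 0, d2 = 0),
                    noise_var = c(1, 2), noise_corr = 0.5,
                    between_B = B,
                    re_var = c(mu1 = 0, mu2 = 0))
  d0 <- sim_design(N = 60, T_occasions = 100, icc_target = NA, seed = 41)
  p0 <- simulate_panel(d0, sp0)
  expect_equal(mean(p0$records$y1), 1.5, tolerance = 0.05)
  expect_equal(mean(p0$records$y2), -0.5, tolerance = 0.05)
  expect_equal(var(p0$records$y1), 1, tolerance = 0.07)
  expect_equal(var(p0$records$y2), 2, tolerance = 0.15)
  expect_equal(cor(p0$records$y1, p0$records$y2), 0.5, tolerance = 0.05)

  # full dynamics without covariate effects: pooled within-person covariance
  # of deviations matches the Lyapunov solution
  spv <- paper_spec(cov_effects = c(c1 = 0, c2 = 0, d1 = 0, d2 = 0),
                    between_B = B, re_var = c(mu1 = 0, mu2 = 0))
  dv <- sim_design(N = 100, T_occasions = 200, icc_target = NA, seed = 43)
  pv <- simulate_panel(dv, spv)
  z <- cbind(pv$records$y1 - 1.5, pv$records$y2 + 0.5)
  expect_equal(cov(z), stationary_moments(spv), tolerance = 0.04)
})

test_that("lag-1 least squares on simulated deviations recovers AR and CR", {
  sp <- paper_spec()
  d <- sim_design(N = 100, T_occasions = 100, icc_target = 0.5, seed = 51)
  pan <- simulate_panel(d, sp)
  rec <- pan$records
  pm1 <- tapply(rec$y1, rec$person_id, mean)[as.character(rec$person_id)]
  pm2 <- tapply(rec$y2, rec$person_id, mean)[as.character(rec$person_id)]
  z1 <- rec$y1 - pm1
  z2 <- rec$y2 - pm2
  i2 <- which(rec$t > 1)
  i1 <- i2 - 1
  f1 <- lm(z1[i2] ~ z1[i1] + z2[i1] + rec$x1[i2] + rec$x2[i2])
  f2 <- lm(z2[i2] ~ z2[i1] + z1[i1] + rec$x1[i2] + rec$x2[i2])
  expect_equal(unname(coef(f1)[2:3]), c(0.4, -0.3), tolerance = 0.03)
  expect_equal(unname(coef(f2)[2:3]), c(0.3, -0.2), tolerance = 0.03)
  expect_equal(unname(coef(f1)[4:5]), c(0.3, -0.5), tolerance = 0.03)
})

test_that("simulation is byte-identical under the same seed", {
  d <- sim_design(N = 10, T_occasions = 20, icc_target = 0.3, seed = 61)
  p1 <- simulate_panel(d, paper_spec())
  p2 <- simulate_panel(d, paper_spec())
  expect_identical(p1$records, p2$records)
  expect_identical(p1$persons, p2$persons)
  p3 <- simulate_panel(sim_design(N = 10, T_occasions = 20,
                                  icc_target = 0.3, seed = 62),
                       paper_spec())
  expect_false(identical(p1$records$y1, p3$records$y1))
})
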