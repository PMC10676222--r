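test_that("the imputation frame carries lags, indicators and all rows", {
  rec <- data.frame(person_id = 1, t = 1:3,
                    y1 = c(10, 20, 30), y2 = c(1, 2, 3),
                    x1 = c(0.1, 0.2, 0.3), x2 = 0)
  p <- panel_data(rec, data.frame(person_id = 1, x3 = 0))
  fr <- build_frame(p)
  expect_equal(fr$y1_lag, c(NA, 10, 20))
  expect_equal(fr$y2_lag, c(NA, 1, 2))
  expect_equal(nrow(fr), 3)
  expect_equal(fr$r_y1, p$mask$y1)

  amp <- mar_panel(sim_small(N = 8, Tn = 12, seed = 81), seed = 2)
  fra <- build_frame(amp)
  expect_identical(fra$r_y1, amp$mask$y1)
  expect_identical(fra$r_x1, amp$mask$x1)
  expect_equal(nrow(fra), nrow(amp$records))
  # lags restart at each person boundary
  expect_true(all(is.na(fra$y1_lag[fra$t == 1])))
})

test_that("imputation preserves observed cells and completes all targets", {
  amp <- mar_panel(sim_small(N = 15, Tn = 25, seed = 83), seed = 4)
  for (method in c("single_level", "multilevel")) {
    cfg <- imputation_config(m = 3, sweeps = 4, method = method, seed = 6)
    cs <- impute_panel(amp, cfg)
    expect_length(cs$panels, 3)
    for (p in cs$panels) {
      expect_false(anyNA(p$records[c("y1", "y2", "x1")]))
      expect_true(all(p$mask == 0))
      for (col in c("y1", "y2", "x1")) {
        obs <- amp$mask[[col]] == 0
        expect_identical(p$records[[col]][obs], amp$records[[col]][obs])
      }
    }
  }
})

test_that("no missingness yields m identical copies of the input", {
  pan <- sim_small(N = 6, Tn = 10, seed = 85)
  cs <- impute_panel(pan, imputation_config(m = 2, sweeps = 2,
                                            method = "single_level",
                                            seed = 3))
  expect_identical(cs$panels[[1]]$records, pan$records)
  expect_identical(cs$panels[[2]]$records, pan$records)
})

test_that("MCAR imputation of an i.i.d. column is mean-unbiased", {
  set.seed(87)
  N <- 40; Tn <- 40
  rec <- data.frame(person_id = rep(1:N, each = Tn),
                    t = rep(1:Tn, N),
                    y1 = rnorm(N * Tn, 5, 1), y2 = rnorm(N * Tn),
                    x1 = rnorm(N * Tn), x2 = rnorm(N * Tn))
  drop <- sample(nrow(rec), 0.3 * nrow(rec))
  truth <- rec$y1
  rec$y1[drop] <- NA
  p <- panel_data(rec, data.frame(person_id = 1:N, x3 = 0))
  fr <- build_frame(p, use_lags = FALSE, indicators = FALSE)
  cs <- impute_single_level(fr, imputation_config(m = 5, sweeps = 3,
                                                  method = "single_level",
                                                  seed = 8))
  imp_means <- sapply(cs$panels, function(q) mean(q$records$y1[drop]))
  expect_equal(mean(imp_means), mean(rec$y1, na.rm = TRUE),
               tolerance = 0.08)
})

test_that("multilevel imputation respects person baselines; single-level is
           pulled toward the grand mean", {
  set.seed(89)
  Tn <- 40
  rec <- data.frame(person_id = rep(1:2, each = Tn), t = rep(1:Tn, 2),
                    y1 = c(rnorm(Tn, -5, 0.1), rnorm(Tn, 5, 0.1)),
                    y2 = rnorm(2 * Tn, 0, 0.1),
                    x1 = rnorm(2 * Tn, 0, 0.1),
                    x2 = rnorm(2 * Tn, 0, 0.1))
  drop <- c(sample(1:Tn, 12), sample(Tn + (1:Tn), 12))
  rec$y1[drop] <- NA
  p <- panel_data(rec, data.frame(person_id = 1:2, x3 = 0))
  fr <- build_frame(p, use_lags = FALSE, indicators = FALSE)
  ml <- impute_multilevel(fr, imputation_config(m = 2, sweeps = 5,
                                                method = "multilevel",
                                                seed = 10))
  sl <- impute_single_level(fr, imputation_config(m = 2, sweeps = 5,
                                                  method = "single_level",
                                                  seed = 10))
  pmean <- ifelse(rec$person_id[drop] == 1, -5, 5)
  dev_ml <- mean(abs(ml$panels[[1]]$records$y1[drop] - pmean))
  dev_sl <- mean(abs(sl$panels[[1]]$records$y1[drop] - pmean))
  expect_lt(dev_ml, 1)       # lands near each person's own mean
  expect_gt(dev_sl, 2)       # shrunk toward the grand mean (0)
  expect_lt(dev_ml, dev_sl)
})

test_that("multilevel completion preserves between-person variance that
           single-level completion understates", {
  pan <- sim_small(N = 40, Tn = 40, seed = 91)
  amp <- mar_panel(pan, seed = 12)
  truth_bv <- var(tapply(pan$records$y1, pan$records$person_id, mean))
  cs_ml <- impute_panel(amp, imputation_config(m = 3, sweeps = 6,
                                               method = "multilevel",
                                               seed = 14))
  cs_sl <- impute_panel(amp, imputation_config(m = 3, sweeps = 6,
                                               method = "single_level",
                                               seed = 14))
  bv <- function(cs) mean(sapply(cs$panels, function(p)
    var(tapply(p$records$y1, p$records$person_id, mean))))
  expect_lt(bv(cs_sl), bv(cs_ml))
  expect_lt(abs(bv(cs_ml) - truth_bv), abs(bv(cs_sl) - truth_bv))
})

test_that("a lagged predictor improves imputation of an autoregressive
           series (11 occasions, points 5, 7, 8, 9 missing)", {
  set.seed(93)
  N <- 150; Tn <- 11; a <- 0.8
  y <- matrix(0, Tn, N)
  y[1, ] <- rnorm(N, 0, sqrt(1 / (1 - a^2)))
  for (t in 2:Tn) y[t, ] <- a * y[t - 1, ] + rnorm(N)
  rec <- data.frame(person_id = rep(1:N, each = Tn), t = rep(1:Tn, N),
                    y1 = as.vector(y), y2 = rnorm(N * Tn, 0, 0.2),
                    x1 = rnorm(N * Tn, 0, 0.2), x2 = rnorm(N * Tn, 0, 0.2))
  truth <- rec$y1
  miss <- rec$t %in% c(5, 7, 8, 9)
  rec$y1[miss] <- NA
  p <- panel_data(rec, data.frame(person_id = 1:N, x3 = 0))
  cfg <- function(s) imputation_config(m = 3, sweeps = 5,
                                       method = "single_level", seed = s)
  with_lag <- impute_single_level(build_frame(p, use_lags = TRUE,
                                              indicators = FALSE), cfg(16))
  no_lag <- impute_single_level(build_frame(p, use_lags = FALSE,
                                            indicators = FALSE), cfg(16))
  mse <- function(cs) mean(sapply(cs$panels, function(q)
    mean((q$records$y1[miss] - truth[miss])^2)))
  expect_lt(mse(with_lag), mse(no_lag))
})

test_that("person-level imputations can be averaged across sets", {
  # direct arithmetic on a completed_set skeleton
  p1 <- tiny_panel(); p2 <- tiny_panel()
  p1$persons$x3[2] <- 0.2
  p2$persons$x3[2] <- 0.4
  cs <- structure(list(panels = list(p1, p2), method = "single_level",
                       m = 2, sweeps = 1, seed = 1,
                       person_miss = list(x3 = 2L), source = tiny_panel()),
                  class = "completed_set")
  out <- average_person_level(cs)
  expect_equal(out$panels[[1]]$persons$x3[2], 0.3)
  expect_equal(out$panels[[2]]$persons$x3[2], 0.3)

  # no person-level missingness: identity
  cs2 <- impute_panel(mar_panel(sim_small(N = 6, Tn = 8, seed = 95),
                                seed = 18),
                      imputation_config(m = 2, sweeps = 2,
                                        method = "single_level", seed = 20))
  out2 <- average_person_level(cs2)
  expect_identical(out2$panels[[1]]$records, cs2$panels[[1]]$records)

  # an incomplete person-level covariate is imputed person-constant and
  # averaging makes all sets agree
  pan <- sim_small(N = 12, Tn = 10, seed = 97)
  pan$persons$x3[c(3, 7)] <- NA
  amp <- mar_panel(pan, seed = 22)
  cs3 <- impute_panel(amp, imputation_config(m = 3, sweeps = 3,
                                             method = "single_level",
                                             seed = 24))
  av <- average_person_level(cs3)
  vals <- sapply(av$panels, function(p) p$persons$x3[c(3, 7)])
  expect_equal(vals[, 1], vals[, 2])
  expect_equal(vals[, 2], vals[, 3])
})

test_that("imputation is deterministic given seed and config", {
  amp <- mar_panel(sim_small(N = 8, Tn = 12, seed = 99), seed = 26)
  cfg <- imputation_config(m = 2, sweeps = 3, method = "multilevel",
                           seed = 28)
  c1 <- impute_panel(amp, cfg)
  c2 <- impute_panel(amp, cfg)
  expect_identical(c1$panels[[1]]$records, c2$panels[[1]]$records)
  expect_identical(c1$panels[[2]]$records, c2$panels[[2]]$records)
})

test_that("a column with zero observed cells is rejected", {
  rec <- data.frame(person_id = rep(1:3, each = 4), t = rep(1:4, 3),
                    y1 = NA_real_, y2 = rnorm(12), x1 = rnorm(12),
                    x2 = rnorm(12))
  p <- panel_data(rec, data.frame(person_id = 1:3, x3 = 0))
  expect_error(impute_panel(p, imputation_config(m = 2, sweeps = 1,
                                                 method = "single_level",
                                                 seed = 1)),
               "zero observed")
})
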