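stamp <- function(s) as.POSIXct(s, tz = "UTC")

test_that("item scoring uses means, sums, and the 0-4 availability recode", {
  r <- score_items(one_record())
  expect_equal(r$urge, 5)            # mean of (5, 5, 5)
  expect_equal(r$neg_affect, 1)      # mean of five 1s
  expect_equal(r$pos_affect, 9)      # sum of three 3s
  expect_equal(r$motivation, 4)
  expect_equal(score_items(one_record(avail = 1))$cig_avail, 0)
  expect_equal(score_items(one_record(avail = 5))$cig_avail, 4)
  # a composite with any missing item is missing
  r2 <- score_items(one_record(urge = c(5, NA, 5)))
  expect_true(is.na(r2$urge))
  expect_equal(r2$neg_affect, 1)
})

test_that("lapse time stamps follow the midpoint and 8-hour rules", {
  now <- stamp("2006-03-01 14:00:00")
  # "0-15 min" option: midpoint 7.5 min before the prompt
  a <- adjust_lapse_time(now, 1L, 2L, stamp("2006-03-01 13:00:00"))
  expect_equal(a$lapse_time, stamp("2006-03-01 13:52:30"))
  expect_equal(a$count, 2L)
  # "8 h or more": unidentifiable, count and time both missing
  b <- adjust_lapse_time(now, 7L, 3L, stamp("2006-03-01 13:00:00"))
  expect_true(is.na(b$lapse_time))
  expect_true(is.na(b$count))
  # midpoint-adjusted time earlier than the previous prompt at 10:00:
  # fall back to the midpoint between prompts, 12:00
  cc <- adjust_lapse_time(now, 6L, 1L, stamp("2006-03-01 10:00:00"))
  expect_equal(cc$lapse_time, stamp("2006-03-01 12:00:00"))
  expect_error(adjust_lapse_time(now, 1L, 1L, now), "precede")
})

test_that("block aggregation averages random-prompt DVs, separates
           self-initiated auxiliaries, and sums lapse counts by block", {
  recs <- rbind(one_record(urge = c(2, 2, 2)), one_record(urge = c(4, 4, 4)),
                one_record(urge = c(5, 5, 5)))
  recs$timestamp <- stamp(c("2006-03-01 13:00:00", "2006-03-01 14:00:00",
                            "2006-03-01 15:00:00"))
  recs$ema_type <- c("random", "random", "slip")
  recs$lapse_count[3] <- 3L
  recs$lapse_timeago[3] <- 1L
  sc <- score_items(recs)
  adj <- adjust_lapse_time(sc$timestamp, sc$lapse_timeago, sc$lapse_count,
                           c(as.POSIXct(NA), sc$timestamp[-3]))
  sc$lapse_time <- adj$lapse_time
  sc$lapse_count_adj <- adj$count
  b <- block_aggregate(sc)
  blk <- b[b$date == as.Date("2006-03-01") & b$block == 3, ]  # 12-18h
  expect_equal(blk$urge, 3)          # mean of the two random prompts only
  expect_equal(blk$aux_urge, 5)      # the slip prompt feeds the auxiliary
  expect_equal(blk$lapse_count, 3)   # slip cigarettes land in this block
  expect_equal(blk$n_src_random, 2)
  # provenance: every non-missing DV cell traces to >= 1 source record
  expect_true(all(b$n_src_random[!is.na(b$urge)] >= 1))
})

test_that("participant filtering applies the 8-occasion boundary", {
  mk <- function(pid, nblocks) {
    ts <- stamp("2006-03-01 08:30:00") + (seq_len(nblocks) - 1) * 6 * 3600
    do.call(rbind, lapply(ts, function(tt) {
      r <- one_record()
      r$person_id <- pid
      r$timestamp <- tt
      r
    }))
  }
  recs <- rbind(mk(1, 7), mk(2, 8))
  sc <- score_items(recs)
  sc$lapse_time <- as.POSIXct(NA)
  sc$lapse_count_adj <- NA_integer_
  b <- block_aggregate(sc)
  f <- filter_participants(b, min_occasions = 8)
  expect_false(1 %in% f$person_id)   # 7 observed blocks: dropped
  expect_true(2 %in% f$person_id)    # exactly 8: retained
  excl <- attr(f, "exclusions")
  expect_equal(excl$below_threshold, 1)
  expect_equal(excl$retained, 1)
})

test_that("detrending removes a linear trend but preserves person means", {
  set.seed(131)
  b <- data.frame(person_id = rep(1:5, each = 20), t = rep(1:20, 5))
  b$urge <- 2 + 0.05 * b$t + rnorm(100, 0, 0.2) +
    rep(rnorm(5), each = 20)
  b$neg_affect <- rep(rnorm(5, 2), each = 20)  # zero slope
  b$urge[sample(100, 10)] <- NA
  pre_mean_u <- tapply(b$urge, b$person_id, mean, na.rm = TRUE)
  pre_mean_n <- tapply(b$neg_affect, b$person_id, mean, na.rm = TRUE)
  out <- detrend_dvs(b)
  expect_equal(tapply(out$urge, out$person_id, mean, na.rm = TRUE),
               pre_mean_u, tolerance = 1e-10)
  expect_equal(tapply(out$neg_affect, out$person_id, mean, na.rm = TRUE),
               pre_mean_n, tolerance = 1e-10)
  # the 0.05/occasion trend is removed (residual slope reflects only the
  # person-mean re-centring under unbalanced missingness)
  sl <- coef(lm(out$urge ~ out$t))[2]
  expect_lt(abs(sl), 0.005)
  # missing cells stay missing
  expect_identical(is.na(out$urge), is.na(b$urge))
  # zero-slope input is unchanged up to numerical noise
  out_n <- detrend_dvs(b, dvs = "neg_affect")
  expect_equal(out_n$neg_affect, b$neg_affect, tolerance = 1e-10)
})

test_that("baseline covariates are standardised and dummy-coded", {
  per <- data.frame(person_id = 1:4,
                    age = c(30, 40, 50, 60),
                    cigs_per_day = c(10, 20, 30, 40),
                    gender = c("female", "male", "female", "male"),
                    race = c("caucasian", "african", "hispanic", "other"),
                    education = c("hs_or_less", "more_than_hs",
                                  "more_than_hs", NA),
                    partner_live = c("no", "yes", "no", "yes"),
                    partner_smoke = c("no", "no", "yes", "no"),
                    time_to_first = c("more_5min", "le_5min", "le_5min",
                                      "more_5min"))
  cc <- code_baseline(per)
  expect_equal(mean(cc$age), 0)
  expect_equal(sd(cc$age), 1)
  expect_equal(cc$male, c(0, 1, 0, 1))
  expect_equal(cc$african, c(0, 1, 0, 0))
  expect_equal(cc$hispanic, c(0, 0, 1, 0))
  expect_equal(cc$other_race, c(0, 0, 0, 1))
  expect_equal(cc$partner_live, c(0, 1, 0, 1))
  expect_equal(cc$partner_smoke, c(0, 0, 1, 0))
  expect_equal(cc$ttf_5min, c(0, 1, 1, 0))
  expect_true(is.na(cc$edu_more_hs[4]))  # missing category stays missing
  per$race[1] <- "martian"
  expect_error(code_baseline(per), "unknown category")
})

test_that("the synthetic stream matches the protocol structure", {
  # full compliance, threshold high enough to suppress self-initiation:
  # exactly 4 prompts per person-day
  st <- synth_ema_stream(n_persons = 5, n_days = 4, compliance = 1,
                         self_threshold = 99, seed = 133)
  cnt <- table(st$person_id, as.Date(st$timestamp))
  expect_true(all(cnt == 4))
  expect_true(all(st$ema_type == "random"))

  # elevation: self-initiated urge exceeds random urge on average
  st2 <- synth_ema_stream(n_persons = 25, n_days = 7, elevation = 1,
                          seed = 135)
  sc <- score_items(st2)
  expect_gt(mean(sc$urge[sc$ema_type != "random"], na.rm = TRUE),
            mean(sc$urge[sc$ema_type == "random"], na.rm = TRUE) + 0.3)
  # strictly increasing time stamps within person
  d <- diff(as.numeric(st2$timestamp))
  same <- st2$person_id[-1] == st2$person_id[-nrow(st2)]
  expect_true(all(d[same] > 0))
  # determinism
  expect_identical(st2, synth_ema_stream(n_persons = 25, n_days = 7,
                                         elevation = 1, seed = 135))
})

test_that("the end-to-end pipeline yields a panel the model machinery
           accepts unchanged", {
  st <- synth_ema_stream(n_persons = 10, n_days = 6, seed = 137)
  prep <- ema_prepare(st)
  expect_identical(validate_panel(prep$panel), character(0))
  expect_true(all(prep$panel$records$t >= 1))
  # 4 blocks per day
  expect_equal(sort(unique(prep$blocks$block)), 1:4)
  # plausible missingness from non-compliance and sleep blocks
  expect_gt(mean(prep$panel$mask$y1), 0.05)
  expect_lt(mean(prep$panel$mask$y1), 0.95)
  # consumable by the imputation and fitting machinery without modification
  cfg <- imputation_config(m = 2, sweeps = 2, method = "multilevel",
                           seed = 7)
  cs <- impute_panel(prep$panel, cfg, auxiliaries = prep$auxiliaries)
  expect_false(anyNA(cs$panels[[1]]$records[c("y1", "y2", "x1")]))
  fit <- fit_mvar(cs$panels[[1]], paper_spec(),
                  settings = fast_settings(seed = 23, iterations = 500,
                                           burn_in = 100, adaptation = 50))
  expect_s3_class(fit, "posterior_draws")
})
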