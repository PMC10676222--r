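#' @name ema_prep
#' @title Ecological momentary assessment preprocessing
#'
#' @description Implements the preprocessing pipeline for time-stamped EMA
#' prompt streams from a smoking-cessation protocol: item scoring, lapse
#' time-stamp adjustment, six-hour block aggregation, participant filtering,
#' dependent-variable detrending and baseline covariate coding. The stream
#' format is a data.frame with columns `person_id`, `timestamp` (POSIXct),
#' `ema_type` (`random`, `urge`, `smoking`, `slip`), urge items
#' `urge1..urge3`, negative-affect items `na1..na5`, `avail` (cigarette
#' availability, 1-5), lapse items `lapse_count` and `lapse_timeago`
#' (response option 1-7), positive-affect items `pa1..pa3`, `selfeff`, and
#' motivation items `motiv1..motiv2`.
NULL

# midpoints (minutes) of the lapse "how long ago" response options:
# 0-15, 15-30, 30-60, 60-120, 120-240, 240-480 min; option 7 = "8 h or
# more" carries no identifiable time and maps to missing.
lapse_timeago_midpoints <- c(7.5, 22.5, 45, 90, 180, 360, NA)

#' Score EMA item responses into composites
#'
#' Urge is the mean of its 3 items and negative affect the mean of its 5
#' items; positive affect is the sum of its 3 items; motivation is the mean
#' of its 2 items; cigarette availability is recoded from the 1-5 response
#' scale to 0-4 to ease interpretation. A composite requires all of its
#' items; otherwise it is missing.
#'
#' @param records EMA stream data.frame (see [ema_prep]).
#' @return The records with composite columns `urge`, `neg_affect`,
#'   `pos_affect`, `motivation`, `cig_avail` appended.
#' @export
score_items <- function(records) {
  all_or_na <- function(m, fn) {
    m <- as.matrix(m)
    out <- fn(m)
    out[rowSums(is.na(m)) > 0] <- NA_real_
    out
  }
  records$urge <- all_or_na(records[paste0("urge", 1:3)], rowMeans)
  records$neg_affect <- all_or_na(records[paste0("na", 1:5)], rowMeans)
  records$pos_affect <- all_or_na(records[paste0("pa", 1:3)], rowSums)
  records$motivation <- all_or_na(records[paste0("motiv", 1:2)], rowMeans)
  records$cig_avail <- records$avail - 1
  records
}

#' Adjust a reported lapse to a usable time stamp
#'
#' The lapse recency item is interval-coded; the lapse time is the current
#' prompt's time stamp minus the midpoint of the chosen interval (e.g. the
#' "0-15 min" option maps to 7.5 min). The "8 h or more" option carries no
#' identifiable time, so both the time and the cigarette count become
#' missing. If the midpoint-adjusted time falls before the previous prompt,
#' the adjusted time is the current time stamp minus half the gap to the
#' previous prompt (i.e. the midpoint between the two prompts).
#'
#' @param timestamp POSIXct of the current prompt.
#' @param timeago_option integer 1-7 response option (NA allowed).
#' @param count reported cigarette count (NA allowed).
#' @param prev_timestamp POSIXct of the previous prompt for the same person
#'   (NA for the first prompt). Must precede `timestamp`.
#' @return list with `lapse_time` (POSIXct or NA) and `count`.
#' @export
adjust_lapse_time <- function(timestamp, timeago_option, count,
                              prev_timestamp = NA) {
  n <- length(timestamp)
  bad <- !is.na(prev_timestamp) & prev_timestamp >= timestamp
  if (any(bad)) stop("previous time stamp must precede the current one")
  mid <- lapse_timeago_midpoints[timeago_option]
  lapse_time <- timestamp - mid * 60
  unid <- !is.na(timeago_option) & timeago_option == 7L
  lapse_time[unid | is.na(timeago_option)] <- NA
  count[unid] <- NA
  before_prev <- !is.na(lapse_time) & !is.na(prev_timestamp) &
    lapse_time < prev_timestamp
  if (any(before_prev)) {
    gap_mid <- (as.numeric(timestamp) - as.numeric(prev_timestamp)) / 2
    lapse_time[before_prev] <- timestamp[before_prev] -
      gap_mid[before_prev]
  }
  list(lapse_time = lapse_time, count = count)
}

block_of_time <- function(ts) {
  # six-hour blocks at local 00:00 / 06:00 / 12:00 / 18:00
  lt <- as.POSIXlt(ts)
  list(date = as.Date(format(ts, "%Y-%m-%d")),
       block = lt$hour %/% 6 + 1L)
}

#' Aggregate scored EMA records into six-hour blocks
#'
#' Every person-day is split into four blocks (12a.m.-6a.m., 6a.m.-12p.m.,
#' 12p.m.-6p.m., 6p.m.-12a.m.). Within a person-block, the dependent
#' variables (urge, negative affect) and cigarette availability are averaged
#' from random prompts only; the auxiliary composites (urge, negative
#' affect, availability from self-initiated prompts, plus positive affect,
#' self-efficacy and motivation from all prompts) are averaged from
#' self-initiated prompts; the lapse count is the sum of reported cigarettes
#' whose adjusted lapse time falls in the block, regardless of source prompt
#' type. Blocks with no contributing prompt hold missing values. Each
#' non-missing cell's source-record count is retained (provenance).
#'
#' @param records scored records ([score_items()]) with columns `lapse_time`
#'   and `lapse_count_adj` from [adjust_lapse_time()].
#' @return A `block_panel` data.frame: `person_id`, `t` (consecutive block
#'   index from each person's first observed day), `date`, `block`, DV and
#'   auxiliary columns, `lapse_count`, and `n_src_*` provenance counts.
#' @export
block_aggregate <- function(records) {
  out <- lapply(split(records, records$person_id), function(rp) {
    bt <- block_of_time(rp$timestamp)
    d0 <- min(bt$date)
    d1 <- max(bt$date)
    ndays <- as.integer(d1 - d0) + 1L
    grid <- data.frame(
      person_id = rp$person_id[1],
      t = seq_len(4L * ndays),
      date = rep(seq(d0, d1, by = 1), each = 4L),
      block = rep(1:4, ndays))
    slot <- (as.integer(bt$date - d0)) * 4L + bt$block
    is_rand <- rp$ema_type == "random"
    is_self <- rp$ema_type != "random"
    agg <- function(v, sel) {
      s <- sel & !is.na(v)
      m <- tapply(v[s], factor(slot[s], levels = grid$t), mean)
      cnt <- tapply(rep(1, sum(s)), factor(slot[s], levels = grid$t), sum)
      list(mean = as.numeric(m), n = as.integer(ifelse(is.na(cnt), 0, cnt)))
    }
    a_urge <- agg(rp$urge, is_rand)
    a_na <- agg(rp$neg_affect, is_rand)
    a_av <- agg(rp$cig_avail, is_rand)
    grid$urge <- a_urge$mean
    grid$neg_affect <- a_na$mean
    grid$cig_avail <- a_av$mean
    grid$n_src_random <- a_urge$n
    s_urge <- agg(rp$urge, is_self)
    grid$aux_urge <- s_urge$mean
    grid$aux_neg_affect <- agg(rp$neg_affect, is_self)$mean
    grid$aux_cig_avail <- agg(rp$cig_avail, is_self)$mean
    grid$pos_affect <- agg(rp$pos_affect, rep(TRUE, nrow(rp)))$mean
    grid$self_efficacy <- agg(rp$selfeff, rep(TRUE, nrow(rp)))$mean
    grid$motivation <- agg(rp$motivation, rep(TRUE, nrow(rp)))$mean
    grid$n_src_self <- s_urge$n
    # lapse counts land in the block of their adjusted time
    lk <- !is.na(rp$lapse_time) & !is.na(rp$lapse_count_adj)
    if (any(lk)) {
      lb <- block_of_time(rp$lapse_time[lk])
      lslot <- (as.integer(lb$date - d0)) * 4L + lb$block
      ok <- lslot >= 1 & lslot <= nrow(grid)
      lc <- tapply(rp$lapse_count_adj[lk][ok],
                   factor(lslot[ok], levels = grid$t), sum)
      grid$lapse_count <- as.numeric(ifelse(is.na(lc), 0, lc))
    } else grid$lapse_count <- 0
    grid
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("block_panel", class(out))
  out
}

#' Filter participants by observed occasions
#'
#' Drops persons with zero prompts (reason `"zero EMAs"`) and persons with
#' fewer than `min_occasions` blocked occasions carrying at least one
#' observed dependent-variable cell (reason `"fewer than 8 occasions"` at
#' the default threshold). Exclusion counts are attached as an attribute.
#'
#' @param blocks a [block_aggregate()] output.
#' @param min_occasions retention threshold (default 8; a person with
#'   exactly 8 observed occasions is retained).
#' @return The filtered `block_panel`, with attribute `exclusions`.
#' @export
filter_participants <- function(blocks, min_occasions = 8) {
  obs <- !is.na(blocks$urge) | !is.na(blocks$neg_affect)
  cnt <- tapply(obs, blocks$person_id, sum)
  src <- tapply(blocks$n_src_random + blocks$n_src_self,
                blocks$person_id, sum)
  zero <- names(cnt)[src == 0]
  few <- setdiff(names(cnt)[cnt < min_occasions], zero)
  keep <- !(blocks$person_id %in% c(zero, few))
  out <- blocks[keep, ]
  attr(out, "exclusions") <- list(
    zero_emas = length(zero),
    below_threshold = length(few),
    retained = length(cnt) - length(zero) - length(few))
  out
}

#' Remove linear time trends from the dependent variables
#'
#' Regresses each dependent variable on the occasion index (one pooled
#' ordinary least squares fit per DV, or one per person with
#' `per_person = TRUE`), takes residuals, and adds each person's pre-detrend
#' mean back, so stationarity is improved while person baselines are
#' preserved exactly. Missing cells stay missing.
#'
#' @param blocks a `block_panel`.
#' @param dvs columns to detrend.
#' @param per_person logical; fit the trend within person instead of pooled.
#' @return The detrended `block_panel`.
#' @export
detrend_dvs <- function(blocks, dvs = c("urge", "neg_affect"),
                        per_person = FALSE) {
  for (dv in dvs) {
    v <- blocks[[dv]]
    ok <- !is.na(v)
    if (length(unique(blocks$t[ok])) < 2)
      stop("degenerate detrending regression for ", dv,
           ": all occasions identical")
    pmean <- stats::ave(v, blocks$person_id,
                        FUN = function(z) mean(z, na.rm = TRUE))
    if (per_person) {
      res <- v
      for (pid in unique(blocks$person_id)) {
        sel <- blocks$person_id == pid & ok
        if (sum(sel) < 2) next
        fit <- stats::lm.fit(cbind(1, blocks$t[sel]), v[sel])
        res[sel] <- fit$residuals
      }
    } else {
      fit <- stats::lm.fit(cbind(1, blocks$t[ok]), v[ok])
      res <- v
      res[ok] <- fit$residuals
    }
    out <- res + pmean
    # re-centre so person means are preserved exactly
    rmean <- stats::ave(out, blocks$person_id,
                        FUN = function(z) mean(z, na.rm = TRUE))
    blocks[[dv]] <- out - rmean + pmean
  }
  blocks
}

#' Code baseline (time-invariant) covariates
#'
#' Continuous covariates (`age`, `cigs_per_day`) are standardised across
#' persons to zero mean and unit variance; categorical covariates are
#' dummy-coded with 1 for male, African American, Hispanic, other race,
#' more than high school, partner lives with you, partner smokes, and 5 min
#' or less to the first cigarette after waking. Missing categorical entries
#' stay missing for downstream imputation.
#'
#' @param persons data.frame with columns `person_id`, `age`,
#'   `cigs_per_day`, `gender` (`"female"`/`"male"`), `race` (`"caucasian"`,
#'   `"african"`, `"hispanic"`, `"other"`), `education`
#'   (`"hs_or_less"`/`"more_than_hs"`), `partner_live`, `partner_smoke`
#'   (`"no"`/`"yes"`), `time_to_first` (`"more_5min"`/`"le_5min"`).
#' @return data.frame of coded covariates keyed by `person_id`.
#' @export
code_baseline <- function(persons) {
  lvl <- function(x, levels) {
    bad <- !is.na(x) & !(x %in% levels)
    if (any(bad)) stop("unknown category label: ",
                       paste(unique(x[bad]), collapse = ", "))
    x
  }
  std <- function(v) as.numeric(scale(v))
  g <- lvl(persons$gender, c("female", "male"))
  r <- lvl(persons$race, c("caucasian", "african", "hispanic", "other"))
  e <- lvl(persons$education, c("hs_or_less", "more_than_hs"))
  pl <- lvl(persons$partner_live, c("no", "yes"))
  ps <- lvl(persons$partner_smoke, c("no", "yes"))
  tf <- lvl(persons$time_to_first, c("more_5min", "le_5min"))
  data.frame(
    person_id = persons$person_id,
    age = std(persons$age),
    cigs_per_day = std(persons$cigs_per_day),
    male = as.integer(g == "male"),
    african = as.integer(r == "african"),
    hispanic = as.integer(r == "hispanic"),
    other_race = as.integer(r == "other"),
    edu_more_hs = as.integer(e == "more_than_hs"),
    partner_live = as.integer(pl == "yes"),
    partner_smoke = as.integer(ps == "yes"),
    ttf_5min = as.integer(tf == "le_5min"))
}

#' Generate a synthetic EMA prompt stream
#'
#' Fixture generator emulating the protocol structure: four random prompts
#' per person-day at random times in waking hours (08:00-22:00) answered
#' with a compliance probability, plus self-initiated slip prompts triggered
#' when a latent urge process crosses a threshold — their item values carry
#' an elevation offset, so self-initiated urge is systematically higher.
#' Lapse reports use the interval-coded recency item. Deterministic given
#' `seed`.
#'
#' @param n_persons,n_days stream size.
#' @param compliance probability a scheduled random prompt is answered.
#' @param elevation mean offset of urge items in self-initiated prompts.
#' @param self_threshold latent-urge threshold triggering a self-initiated
#'   prompt (higher = fewer).
#' @param start date of the first monitoring day.
#' @param seed integer seed.
#' @return An EMA stream data.frame (see [ema_prep]) sorted by person and
#'   time, with strictly increasing time stamps within person.
#' @export
synth_ema_stream <- function(n_persons = 20, n_days = 7, compliance = 0.8,
                             elevation = 1.0, self_threshold = 1.0,
                             start = as.Date("2006-03-01"), seed = 1L) {
  set.seed(as.integer(seed))
  item <- function(mu, k) pmin(5, pmax(1, round(mu + stats::rnorm(k, 0, 0.7))))
  rows <- list()
  for (i in seq_len(n_persons)) {
    base_urge <- stats::rnorm(1, 3, 0.6)
    base_na <- stats::rnorm(1, 2.5, 0.5)
    lat <- 0
    for (d in seq_len(n_days)) {
      # 4 scheduled prompts in the 4 waking quarters of 08:00-22:00
      hrs <- sort(8 + 3.5 * (0:3) + stats::runif(4, 0, 3.5))
      for (h in hrs) {
        lat <- 0.6 * lat + stats::rnorm(1, 0, 0.6)
        ts <- as.POSIXct(start + (d - 1), tz = "UTC") + h * 3600
        if (stats::runif(1) < compliance) {
          u <- base_urge + lat
          rows[[length(rows) + 1]] <- ema_row(i, ts, "random", u,
                                              base_na + 0.3 * lat)
        }
        if (lat > self_threshold) {
          ts2 <- ts + stats::runif(1, 600, 3000)
          u <- base_urge + lat + elevation
          r <- ema_row(i, ts2, "slip", u, base_na + 0.3 * lat + 0.3)
          r$lapse_count <- stats::rpois(1, 2) + 1L
          r$lapse_timeago <- sample(1:7, 1, prob = c(4, 3, 2, 1, 1, 1, 1))
          rows[[length(rows) + 1]] <- r
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$person_id, out$timestamp), ]
  # enforce strictly increasing time stamps within person
  dup <- c(FALSE, diff(as.numeric(out$timestamp)) <= 0 &
             out$person_id[-1] == out$person_id[-nrow(out)])
  out$timestamp[dup] <- out$timestamp[dup] + 1
  rownames(out) <- NULL
  out
}

ema_row <- function(pid, ts, type, urge_mu, na_mu) {
  item <- function(mu, k) pmin(5, pmax(1, round(mu + stats::rnorm(k, 0, 0.7))))
  df <- data.frame(person_id = pid, timestamp = ts, ema_type = type)
  df[paste0("urge", 1:3)] <- as.list(item(urge_mu, 3))
  df[paste0("na", 1:5)] <- as.list(item(na_mu, 5))
  df$avail <- item(3, 1)
  df$lapse_count <- NA_integer_
  df$lapse_timeago <- NA_integer_
  df[paste0("pa", 1:3)] <- as.list(item(3, 3))
  df$selfeff <- item(3.5, 1)
  df[paste0("motiv", 1:2)] <- as.list(item(4, 2))
  df
}

#' Run the full EMA preprocessing pipeline
#'
#' Scores items, adjusts lapse time stamps, aggregates into six-hour blocks,
#' filters participants, detrends the dependent variables, and maps the
#' result into an [panel_data()] ready for imputation and model fitting:
#' `y1` = urge, `y2` = negative affect, `x1` = cigarette availability,
#' `x2` = blocked lapse count (blocks without any reported lapse count 0 —
#' no report means no recorded cigarettes). Auxiliary block columns from
#' self-initiated prompts are returned alongside for the imputation model.
#'
#' @param records an EMA stream (see [ema_prep]).
#' @param persons optional baseline covariate table passed through
#'   [code_baseline()]; defaults to an intercept-only persons table.
#' @param min_occasions participant filter threshold.
#' @return list with `panel` (an `mvar_panel`), `auxiliaries` (data.frame
#'   keyed by `person_id`, `t`), `blocks` (the filtered, detrended
#'   `block_panel`) and `exclusions`.
#' @export
ema_prepare <- function(records, persons = NULL, min_occasions = 8) {
  sc <- score_items(records)
  prev <- c(as.POSIXct(NA), sc$timestamp[-nrow(sc)])
  prev[c(TRUE, sc$person_id[-1] != sc$person_id[-nrow(sc)])] <- NA
  adj <- adjust_lapse_time(sc$timestamp, sc$lapse_timeago, sc$lapse_count,
                           prev)
  sc$lapse_time <- adj$lapse_time
  sc$lapse_count_adj <- adj$count
  blocks <- block_aggregate(sc)
  blocks <- filter_participants(blocks, min_occasions)
  excl <- attr(blocks, "exclusions")
  blocks <- detrend_dvs(blocks)
  recs <- data.frame(person_id = blocks$person_id, t = blocks$t,
                     y1 = blocks$urge, y2 = blocks$neg_affect,
                     x1 = blocks$cig_avail, x2 = blocks$lapse_count)
  if (is.null(persons))
    persons <- data.frame(person_id = unique(recs$person_id))
  persons <- persons[persons$person_id %in% unique(recs$person_id), ,
                     drop = FALSE]
  aux <- blocks[c("person_id", "t", "aux_urge", "aux_neg_affect",
                  "aux_cig_avail", "pos_affect", "self_efficacy",
                  "motivation")]
  list(panel = panel_data(recs, persons,
                          meta = list(tag = "ema_prepare")),
       auxiliaries = aux, blocks = blocks, exclusions = excl)
}
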