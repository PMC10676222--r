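#' Calibrate the amputation intercept to a target missingness rate
#'
#' Finds the logit-scale intercept `psi0` such that the average missingness
#' probability `mean(plogis(psi0 + slope * x2))` over all person-times equals
#' `target_rate`, by monotone root-finding (the mean probability is strictly
#' increasing in `psi0`).
#'
#' @param panel an [panel_data()] whose `x2` column is fully observed.
#' @param slope logit-scale slope on `x2`.
#' @param target_rate target proportion of missing cells, in (0, 1).
#' @return The calibrated intercept (numeric scalar); the achieved mean
#'   probability matches `target_rate` to within 1e-6.
#' @export
calibrate_intercept <- function(panel, slope, target_rate) {
  if (target_rate <= 0 || target_rate >= 1)
    stop("target_rate must be in (0, 1)")
  x2 <- panel$records$x2
  if (anyNA(x2)) stop("x2 must be fully observed for calibration")
  f <- function(p0) mean(stats::plogis(p0 + slope * x2)) - target_rate
  lo <- -40; hi <- 40
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Impose missing-at-random missingness on a complete panel
#'
#' For each person-time, the two dependent variables are jointly set missing
#' (one prompt missed means both items missing) with probability
#' `plogis(psi0_dv + psi1 * x2)`, and `x1` independently with probability
#' `plogis(psi0_x1 + psi_x2 * x2)`. `x2` and the person-level covariates are
#' never amputated, so the mechanism is MAR given the observed data.
#' Deterministic given `seed`; observed values are never altered.
#'
#' @param panel a complete [panel_data()].
#' @param model a [missingness_model()].
#' @param seed integer seed.
#' @param joint_dv logical; `FALSE` draws the two DV indicators independently
#'   instead of jointly (default `TRUE`, one draw per occasion).
#' @return The panel with `NA` cells and an updated mask.
#' @export
apply_mar <- function(panel, model, seed, joint_dv = TRUE) {
  rec <- panel$records
  if (anyNA(rec$x2)) stop("apply_mar requires fully observed x2")
  set.seed(as.integer(seed))
  n <- nrow(rec)
  p_dv <- stats::plogis(model$psi0_dv + model$psi1 * rec$x2)
  p_x1 <- stats::plogis(model$psi0_x1 + model$psi_x2 * rec$x2)
  if (joint_dv) {
    r_dv <- stats::runif(n) < p_dv
    r_y1 <- r_dv; r_y2 <- r_dv
  } else {
    r_y1 <- stats::runif(n) < p_dv
    r_y2 <- stats::runif(n) < p_dv
  }
  r_x1 <- stats::runif(n) < p_x1
  rec$y1[r_y1] <- NA_real_
  rec$y2[r_y2] <- NA_real_
  rec$x1[r_x1] <- NA_real_
  meta <- panel$meta
  meta$amputation <- list(model = model, seed = as.integer(seed),
                          joint_dv = joint_dv)
  panel_data(rec, panel$persons, meta = meta)
}
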