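#' Simulation design for a multi-subject panel
#'
#' @param N number of persons (>= 2). The study's "small N" is 30; "large N"
#'   defaults to 100.
#' @param T_occasions occasions per person (>= 3); small/large levels are
#'   10 and 100.
#' @param icc_target desired proportion of total DV variance attributable to
#'   between-person intercept differences, in `[0, 1)`; conventional high/low
#'   contrast 0.5 / 0.1. `NA` leaves the spec's random-effect variances as
#'   given instead of calibrating them.
#' @param burn_in_steps warm-up steps simulated and discarded before the first
#'   recorded occasion.
#' @param seed integer seed controlling the whole panel draw.
#' @return Object of class `sim_design`.
#' @export
sim_design <- function(N = 100, T_occasions = 100, icc_target = 0.5,
                       burn_in_steps = 50, seed = 1L) {
  stopifnot(N >= 2, T_occasions >= 3, burn_in_steps >= 0)
  if (!is.na(icc_target)) stopifnot(icc_target >= 0, icc_target < 1)
  structure(list(N = as.integer(N), T_occasions = as.integer(T_occasions),
                 icc_target = icc_target,
                 burn_in_steps = as.integer(burn_in_steps),
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' Simulate the covariate panel
#'
#' Generates the two time-varying covariates as univariate AR(1) processes
#' with no between-person heterogeneity (within-person variation only),
#' started from their stationary distributions, and the person-level covariate
#' `x3` i.i.d. normal. Deterministic given `design$seed`.
#'
#' @param design a [sim_design()].
#' @param spec an [mvar_spec()]; its `cov_gen` field supplies the AR
#'   coefficients, innovation variances and `x3` scale.
#' @return list with `x` (records data.frame `person_id`, `t`, `x1`, `x2`,
#'   including `design$burn_in_steps` warm-up rows with `t <= 0`) and
#'   `persons` (data.frame `person_id`, `x3`).
#' @export
simulate_covariates <- function(design, spec) {
  if (any(abs(spec$cov_gen$ar) >= 1))
    stop("covariate generator is non-stationary")
  set.seed(design$seed)
  N <- design$N
  Ttot <- design$T_occasions + design$burn_in_steps
  arx <- spec$cov_gen$ar
  sv <- spec$cov_gen$noise_var
  gen_ar1 <- function(a, s2) {
    # one column per person, stationary start
    x <- matrix(0, Ttot, N)
    x[1, ] <- stats::rnorm(N, 0, sqrt(s2 / (1 - a^2)))
    if (Ttot > 1) {
      e <- matrix(stats::rnorm((Ttot - 1) * N, 0, sqrt(s2)), Ttot - 1, N)
      for (t in 2:Ttot) x[t, ] <- a * x[t - 1, ] + e[t - 1, ]
    }
    x
  }
  x1 <- gen_ar1(arx[1], sv[1])
  x2 <- gen_ar1(arx[2], sv[2])
  x3 <- stats::rnorm(N, 0, spec$cov_gen$x3_sd)
  list(x = data.frame(person_id = rep(seq_len(N), each = Ttot),
                      t = rep(seq_len(Ttot) - design$burn_in_steps, N),
                      x1 = as.vector(x1), x2 = as.vector(x2)),
       persons = data.frame(person_id = seq_len(N), x3 = x3))
}

#' Random-intercept variance achieving a target ICC
#'
#' Computes the random-intercept variance `Delta_mu` (per dependent variable)
#' such that `Delta_mu / (Delta_mu + V_within)` equals `icc_target`, where
#' `V_within` is the stationary within-person variance of the dependent
#' variable given its person mean — the noise-driven Lyapunov variance plus
#' the contribution of the AR(1) time-varying covariates, both propagated
#' exactly through the VAR dynamics (augmented-state Lyapunov solution).
#'
#' @param spec a stationary [mvar_spec()].
#' @param icc_target proportion in `[0, 1)`.
#' @return length-2 numeric of random-intercept variances (one per DV).
#' @export
solve_re_variance_for_icc <- function(spec, icc_target) {
  stopifnot(icc_target >= 0, icc_target < 1)
  Vw <- diag(stationary_variance_augmented(spec))[1:2]
  icc_target / (1 - icc_target) * Vw
}

#' Simulate a complete multilevel VAR(1) panel
#'
#' Draws person-specific parameters from the between-level model
#' (`between_B` applied to `(1, x3)` plus independent normal random effects),
#' simulates the covariates via [simulate_covariates()], runs the within-person
#' VAR(1) recursion with bivariate normal process noise from a
#' stationary-distribution start, discards `burn_in_steps` warm-up occasions,
#' and returns a complete panel (mask all zero). Fully deterministic given
#' `(design$seed, design, spec)`.
#'
#' If `design$icc_target` is not `NA`, the random-intercept variances in
#' `spec` are first replaced by [solve_re_variance_for_icc()] output so the
#' panel realises the designed intraclass correlation.
#'
#' @param design a [sim_design()].
#' @param spec an [mvar_spec()].
#' @return An [panel_data()] object with `meta$seed`, `meta$spec` recorded.
#' @export
simulate_panel <- function(design, spec) {
  viol <- validate_spec(spec)
  if (length(viol)) stop("invalid spec: ", paste(viol, collapse = "; "))
  if (!is.na(design$icc_target)) {
    dm <- solve_re_variance_for_icc(spec, design$icc_target)
    spec$re_var["mu1"] <- dm[1]
    spec$re_var["mu2"] <- dm[2]
  }
  cov <- simulate_covariates(design, spec)  # seeds the RNG stream
  N <- design$N
  Tn <- design$T_occasions
  Ttot <- Tn + design$burn_in_steps
  Xb <- cbind(1, cov$persons$x3)

  pp <- person_param_names(spec$random_var_params)
  theta <- Xb %*% t(spec$between_B) +
    matrix(stats::rnorm(N * length(pp)), N) %*% diag(sqrt(spec$re_var),
                                                     length(pp))
  colnames(theta) <- pp
  Sig <- noise_cov(spec)
  Schol <- chol(Sig)
  ce <- spec$cov_effects
  Cm <- matrix(c(ce["c1"], ce["c2"], ce["d1"], ce["d2"]), 2, 2)

  x1m <- matrix(cov$x$x1, Ttot, N)
  x2m <- matrix(cov$x$x2, Ttot, N)
  z1 <- matrix(0, Ttot, N)
  z2 <- matrix(0, Ttot, N)
  if (spec$random_var_params) {
    a1 <- theta[, "ar1"]; a2 <- theta[, "ar2"]
    c1r <- theta[, "cr1"]; c2r <- theta[, "cr2"]
  } else {
    a1 <- rep(spec$ar[1], N); a2 <- rep(spec$ar[2], N)
    c1r <- rep(spec$cr[1], N); c2r <- rep(spec$cr[2], N)
  }
  V0 <- stationary_moments(spec)
  z0 <- matrix(stats::rnorm(2 * N), N) %*% chol(V0)
  zeta <- array(stats::rnorm(2 * Ttot * N), c(Ttot * N, 2)) %*% Schol
  zeta1 <- matrix(zeta[, 1], Ttot, N)
  zeta2 <- matrix(zeta[, 2], Ttot, N)
  prev1 <- z0[, 1]; prev2 <- z0[, 2]
  for (t in seq_len(Ttot)) {
    z1[t, ] <- a1 * prev1 + c1r * prev2 +
      Cm[1, 1] * x1m[t, ] + Cm[1, 2] * x2m[t, ] + zeta1[t, ]
    z2[t, ] <- a2 * prev2 + c2r * prev1 +
      Cm[2, 1] * x1m[t, ] + Cm[2, 2] * x2m[t, ] + zeta2[t, ]
    prev1 <- z1[t, ]; prev2 <- z2[t, ]
  }
  keep <- (design$burn_in_steps + 1):Ttot
  y1 <- sweep(z1[keep, , drop = FALSE], 2, theta[, "mu1"], `+`)
  y2 <- sweep(z2[keep, , drop = FALSE], 2, theta[, "mu2"], `+`)
  records <- data.frame(person_id = rep(seq_len(N), each = Tn),
                        t = rep(seq_len(Tn), N),
                        y1 = as.vector(y1), y2 = as.vector(y2),
                        x1 = as.vector(x1m[keep, , drop = FALSE]),
                        x2 = as.vector(x2m[keep, , drop = FALSE]))
  panel_data(records, cov$persons,
             meta = list(seed = design$seed, tag = "simulate_panel",
                         spec = spec, design = design,
                         true_params = theta))
}
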