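#' Generative specification of a multilevel bivariate VAR(1) model
#'
#' Bundles every quantity needed to generate (and to fit) a two-variable
#' multilevel VAR(1) process. Within person, deviations from person-specific
#' baselines follow
#' \deqn{y_{1,t} - \mu_1 = ar_1 (y_{1,t-1} - \mu_1) + cr_1 (y_{2,t-1} - \mu_2)
#'   + c_1 x_{1,t} + d_1 x_{2,t} + \zeta_{1,t}}
#' and symmetrically for the second variable, with bivariate normal process
#' noise (variances `noise_var`, correlation `noise_corr`). Between persons,
#' the person-specific parameters are regressed on time-invariant covariates
#' through `between_B`, with independent normal random effects of variances
#' `re_var`.
#'
#' @param ar length-2 autoregression coefficients (variable on its own lag).
#' @param cr length-2 cross-regression coefficients (variable on the other
#'   variable's lag); `cr[1]` enters the first equation.
#' @param cov_effects length-4 numeric `(c1, c2, d1, d2)`: effects of the two
#'   time-varying covariates on each dependent variable.
#' @param noise_var length-2 process-noise variances, both positive.
#' @param noise_corr process-noise correlation in (-1, 1).
#' @param between_B coefficient matrix, one row per person-specific parameter
#'   (rows `mu1, mu2` and, when `random_var_params = TRUE`, also
#'   `ar1, ar2, cr1, cr2`), one column per between-level design column
#'   (intercept first, then time-invariant covariates).
#' @param re_var random-effect variances, one per row of `between_B`
#'   (diagonal random-effect covariance; see Details).
#' @param random_var_params logical; if `TRUE` the AR/CR coefficients are
#'   person-specific with their own between-level rows, otherwise they are
#'   fixed across persons (the simulation-study variant).
#' @param cov_gen list describing the covariate generators: `ar` (length-2
#'   AR(1) coefficients for x1, x2), `noise_var` (their innovation variances)
#'   and `x3_sd` (standard deviation of the person-level covariate).
#'
#' @details Random effects are mutually independent across person-specific
#' parameters (a diagonal random-effect covariance); this matches reporting of
#' random-effect variances only. The person-specific parameter ordering is
#' fixed as `(mu1, mu2, ar1, ar2, cr1, cr2)`. The between-level link is the
#' identity.
#'
#' @return An object of class `mvar_spec`.
#' @seealso [validate_spec()], [stationary_moments()], [simulate_panel()]
#' @export
#' @examples
#' sp <- mvar_spec()
#' validate_spec(sp)
#' stationary_moments(sp)
mvar_spec <- function(ar = c(0.4, 0.3),
                      cr = c(-0.3, -0.2),
                      cov_effects = c(c1 = 0.3, c2 = 0.3, d1 = -0.5, d2 = -0.4),
                      noise_var = c(1, 1),
                      noise_corr = 0.3,
                      between_B = NULL,
                      re_var = NULL,
                      random_var_params = FALSE,
                      cov_gen = list(ar = c(0.3, 0.3), noise_var = c(1, 1),
                                     x3_sd = 1)) {
  pp <- person_param_names(random_var_params)
  if (is.null(between_B)) {
    between_B <- matrix(0, nrow = length(pp), ncol = 2,
                        dimnames = list(pp, c("(Intercept)", "x3")))
    between_B["mu1", ] <- c(2.0, 0.3)
    between_B["mu2", ] <- c(2.0, 0.3)
    if (random_var_params) {
      between_B["ar1", 1] <- ar[1]
      between_B["ar2", 1] <- ar[2]
      between_B["cr1", 1] <- cr[1]
      between_B["cr2", 1] <- cr[2]
    }
  }
  if (is.null(rownames(between_B))) rownames(between_B) <- pp
  if (is.null(re_var)) {
    re_var <- stats::setNames(rep(0, length(pp)), pp)
    re_var[c("mu1", "mu2")] <- 1
    if (random_var_params) re_var[c("ar1", "ar2", "cr1", "cr2")] <- 0.01
  }
  if (is.null(names(re_var))) names(re_var) <- pp
  structure(
    list(ar = as.numeric(ar), cr = as.numeric(cr),
         cov_effects = stats::setNames(as.numeric(cov_effects),
                                       c("c1", "c2", "d1", "d2")),
         noise_var = as.numeric(noise_var),
         noise_corr = as.numeric(noise_corr),
         between_B = between_B, re_var = re_var,
         random_var_params = isTRUE(random_var_params),
         cov_gen = cov_gen),
    class = "mvar_spec")
}

person_param_names <- function(random_var_params) {
  if (random_var_params) c("mu1", "mu2", "ar1", "ar2", "cr1", "cr2")
  else c("mu1", "mu2")
}

#' Within-person transition matrix of an `mvar_spec`
#'
#' @param spec an [mvar_spec()].
#' @return The 2x2 matrix `A = rbind(c(ar1, cr1), c(cr2, ar2))` acting on
#'   lagged deviations `(y1 - mu1, y2 - mu2)`.
#' @export
transition_matrix <- function(spec) {
  matrix(c(spec$ar[1], spec$cr[2], spec$cr[1], spec$ar[2]), 2, 2)
}

#' Process-noise covariance of an `mvar_spec`
#'
#' @param spec an [mvar_spec()].
#' @return The 2x2 covariance `Sigma` with diagonal `noise_var` and
#'   off-diagonal `noise_corr * sigma1 * sigma2`.
#' @export
noise_cov <- function(spec) {
  s <- sqrt(spec$noise_var)
  off <- spec$noise_corr * s[1] * s[2]
  matrix(c(spec$noise_var[1], off, off, spec$noise_var[2]), 2, 2)
}

#' Validate a model specification
#'
#' Checks positivity of the noise variances, the admissible range of the
#' noise correlation, positive semi-definiteness of the (diagonal)
#' random-effect covariance, stationarity of the within-person transition
#' matrix (spectral radius strictly below one), and stationarity of the
#' covariate generators. Violations are reported, not thrown.
#'
#' @param spec an [mvar_spec()].
#' @return A character vector of violations; empty when the spec is valid.
#' @export
validate_spec <- function(spec) {
  out <- character()
  if (length(spec$ar) != 2 || length(spec$cr) != 2)
    out <- c(out, "ar and cr must each have length 2")
  if (any(!is.finite(c(spec$ar, spec$cr, spec$cov_effects,
                       spec$noise_var, spec$noise_corr))))
    out <- c(out, "non-finite parameter value")
  if (any(spec$noise_var <= 0))
    out <- c(out, "noise_var: variances must be strictly positive")
  if (abs(spec$noise_corr) >= 1)
    out <- c(out, "noise_corr out of range (-1, 1)")
  if (any(spec$re_var < 0))
    out <- c(out, "re_var: random-effect variances must be non-negative")
  pp <- person_param_names(spec$random_var_params)
  if (!identical(rownames(spec$between_B), pp) ||
      !identical(names(spec$re_var), pp))
    out <- c(out, "between_B rows / re_var names must follow the (mu1, mu2, ar1, ar2, cr1, cr2) ordering")
  if (length(spec$ar) == 2 && length(spec$cr) == 2 &&
      all(is.finite(c(spec$ar, spec$cr)))) {
    rho <- max(Mod(eigen(transition_matrix(spec), only.values = TRUE)$values))
    if (rho >= 1) out <- c(out, "stationarity violated: spectral radius of the transition matrix is >= 1")
  }
  if (any(abs(spec$cov_gen$ar) >= 1))
    out <- c(out, "cov_gen: covariate AR(1) coefficients must be in (-1, 1)")
  if (any(spec$cov_gen$noise_var <= 0))
    out <- c(out, "cov_gen: covariate innovation variances must be positive")
  out
}

#' Stationary covariance of the within-person deviation process
#'
#' Solves the discrete Lyapunov equation `V = A V A' + Sigma` for the
#' stationary covariance of the deviations `(y1 - mu1, y2 - mu2)` with the
#' covariate effects excluded (pure noise-driven process).
#'
#' @param spec a stationary [mvar_spec()].
#' @return A 2x2 covariance matrix.
#' @export
stationary_moments <- function(spec) {
  viol <- validate_spec(spec)
  if (any(grepl("stationarity", viol)))
    stop("stationary_moments: spec is not stationary")
  A <- transition_matrix(spec)
  dlyap_solve(A, noise_cov(spec))
}

# vec-form solver for V = A V A' + Q
dlyap_solve <- function(A, Q) {
  k <- nrow(A)
  vecV <- solve(diag(k * k) - kronecker(A, A), as.vector(Q))
  matrix(vecV, k, k)
}

# Stationary covariance of the augmented state (z1, z2, x1, x2), where the
# deviations z are driven both by the process noise and by the AR(1)
# covariates through the contemporaneous effects C. Used for ICC calibration:
# the within-person variance of y given mu is the (1,1)/(2,2) block.
stationary_variance_augmented <- function(spec) {
  A <- transition_matrix(spec)
  ce <- spec$cov_effects
  C <- matrix(c(ce["c1"], ce["c2"], ce["d1"], ce["d2"]), 2, 2)
  Ax <- diag(spec$cov_gen$ar, 2)
  Se <- diag(spec$cov_gen$noise_var, 2)
  # s_t = T s_{t-1} + w_t; x_t = Ax x_{t-1} + e_t and
  # z_t = A z_{t-1} + C x_t + zeta_t = A z_{t-1} + C Ax x_{t-1} + (C e_t + zeta_t)
  Tm <- rbind(cbind(A, C %*% Ax), cbind(matrix(0, 2, 2), Ax))
  Qw <- rbind(cbind(C %*% Se %*% t(C) + noise_cov(spec), C %*% Se),
              cbind(Se %*% t(C), Se))
  dlyap_solve(Tm, Qw)
}

#' @export
print.mvar_spec <- function(x, ...) {
  kind <- if (x$random_var_params) "random intercepts + random VAR parameters"
          else "random intercepts only"
  cat("Multilevel bivariate VAR(1) specification (", kind, ")\n", sep = "")
  cat("  ar = (", paste(x$ar, collapse = ", "), "), cr = (",
      paste(x$cr, collapse = ", "), ")\n", sep = "")
  cat("  covariate effects (c1, c2, d1, d2) = (",
      paste(x$cov_effects, collapse = ", "), ")\n", sep = "")
  cat("  noise variances = (", paste(x$noise_var, collapse = ", "),
      "), correlation = ", x$noise_corr, "\n", sep = "")
  cat("  random-effect variances: ",
      paste(names(x$re_var), round(x$re_var, 4), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
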