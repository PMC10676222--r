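#' Prior settings for the multilevel VAR sampler
#'
#' Weakly informative defaults: normal(0, variance 100) for every
#' between-level coefficient, uniform(0, 100) for between-level random-effect
#' variances, normal(0, variance 10) for VAR coefficients when they are fixed
#' rather than random, normal(0, variance 1) for the covariate effects,
#' uniform(0, 100) for the process-noise variances and uniform(-1, 1) for
#' their correlation. All overridable.
#'
#' @param between_fixed_var,fixed_var_params_var,cov_effects_var prior
#'   variances for the normal priors.
#' @param noise_var_upper,re_var_upper upper bounds of the uniform variance
#'   priors.
#' @return Object of class `prior_set`.
#' @export
prior_set <- function(between_fixed_var = 100, fixed_var_params_var = 10,
                      cov_effects_var = 1, noise_var_upper = 100,
                      re_var_upper = 100) {
  stopifnot(between_fixed_var > 0, fixed_var_params_var > 0,
            cov_effects_var > 0, noise_var_upper > 0, re_var_upper > 0)
  structure(list(between_fixed_var = between_fixed_var,
                 fixed_var_params_var = fixed_var_params_var,
                 cov_effects_var = cov_effects_var,
                 noise_var_upper = noise_var_upper,
                 re_var_upper = re_var_upper),
            class = "prior_set")
}

#' MCMC settings
#'
#' The full-scale defaults mirror the empirical analysis protocol
#' (4000 adaptation, 1000 burn-in, 15000 iterations, thinning 2). The
#' bespoke Gibbs/slice sampler needs no adaptive tuning, so adaptation
#' iterations are simply additional discarded warm-up; the retained draw
#' count per chain is `(iterations - burn_in) / thin`.
#'
#' @param adaptation,burn_in,iterations,thin,chains,seed positive integers;
#'   `chains >= 2`, `iterations > burn_in`, `thin >= 1`.
#' @return Object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(adaptation = 4000, burn_in = 1000,
                          iterations = 15000, thin = 2, chains = 2,
                          seed = 1L) {
  stopifnot(adaptation >= 0, burn_in >= 1, iterations > burn_in, thin >= 1,
            chains >= 2)
  structure(list(adaptation = as.integer(adaptation),
                 burn_in = as.integer(burn_in),
                 iterations = as.integer(iterations),
                 thin = as.integer(thin), chains = as.integer(chains),
                 seed = as.integer(seed)),
            class = "mcmc_settings")
}

#' Scaled-down MCMC settings for simulation-study fits
#'
#' Desk-scale protocol used by the Monte Carlo study: 2 chains, 500
#' adaptation, 500 burn-in, 2000 iterations, no thinning. Convergence
#' diagnostics gate validity at this scale.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [mcmc_settings()].
#' @return An `mcmc_settings` object.
#' @export
mcmc_settings_study <- function(seed = 1L, ...) {
  args <- utils::modifyList(list(adaptation = 500, burn_in = 500,
                                 iterations = 2000, thin = 1, chains = 2,
                                 seed = seed), list(...))
  do.call(mcmc_settings, args)
}

param_names_fit <- function(random_var, xb_names, augment) {
  pp <- if (random_var) c("mu1", "mu2", "ar1", "ar2", "cr1", "cr2")
        else c("mu1", "mu2")
  nm <- c(as.vector(t(outer(pp, xb_names,
                            function(a, b) paste0("b_", a, "_", b)))),
          paste0("delta2_", pp))
  if (!random_var) nm <- c(nm, "ar1", "ar2", "cr1", "cr2")
  nm <- c(nm, "c1", "c2", "d1", "d2", "sigma2_1", "sigma2_2", "rho")
  if (augment) nm <- c(nm, "x_ar", "x_var")
  nm
}

build_indices <- function(panel) {
  rec <- panel$records
  ord <- order(rec$person_id, rec$t)
  stopifnot(identical(ord, seq_len(nrow(rec))))
  pid <- match(rec$person_id, panel$persons$person_id) - 1L
  newp <- c(TRUE, rec$person_id[-1] != rec$person_id[-nrow(rec)])
  prev <- seq_len(nrow(rec)) - 2L   # 0-based previous row
  prev[newp] <- -1L
  list(pid = pid, prev = prev)
}

default_inits <- function(panel, Xb, random_var) {
  rec <- panel$records
  idx <- build_indices(panel)
  mu <- cbind(tapply(rec$y1, rec$person_id, mean, na.rm = TRUE),
              tapply(rec$y2, rec$person_id, mean, na.rm = TRUE))
  mu[!is.finite(mu)] <- mean(rec$y1, na.rm = TRUE)
  # pooled lag-1 least squares on deviations for (ar, cr, c, d)
  z1 <- rec$y1 - mu[idx$pid + 1L, 1]
  z2 <- rec$y2 - mu[idx$pid + 1L, 2]
  tgt <- which(idx$prev >= 0)
  pv <- idx$prev[tgt] + 1L
  X <- cbind(z1[pv], z2[pv], rec$x1[tgt], rec$x2[tgt])
  ok <- stats::complete.cases(X, z1[tgt], z2[tgt])
  cf1 <- tryCatch(stats::lm.fit(X[ok, , drop = FALSE], z1[tgt][ok])$coef,
                  error = function(e) c(0.1, 0, 0, 0))
  cf2 <- tryCatch(stats::lm.fit(X[ok, c(2, 1, 3, 4), drop = FALSE],
                                z2[tgt][ok])$coef,
                  error = function(e) c(0.1, 0, 0, 0))
  cf1[!is.finite(cf1)] <- 0
  cf2[!is.finite(cf2)] <- 0
  ar <- c(cf1[1], cf2[1]); cr <- c(cf1[2], cf2[2])
  cd <- c(cf1[3], cf2[3], cf1[4], cf2[4])  # c1 c2 d1 d2
  e1 <- z1[tgt] - X %*% cf1
  e2 <- z2[tgt] - X[, c(2, 1, 3, 4)] %*% cf2
  s1 <- stats::var(e1[is.finite(e1)]); s2 <- stats::var(e2[is.finite(e2)])
  r0 <- suppressWarnings(stats::cor(e1[is.finite(e1) & is.finite(e2)],
                                    e2[is.finite(e1) & is.finite(e2)]))
  if (!is.finite(r0)) r0 <- 0
  nb <- if (random_var) 6 else 2
  B <- matrix(0, nb, ncol(Xb))
  for (d in 1:2) B[d, ] <- stats::lm.fit(Xb, mu[, d])$coef
  B[!is.finite(B)] <- 0
  delta2 <- rep(0.5, nb)
  for (d in 1:2)
    delta2[d] <- max(stats::var(mu[, d] - Xb %*% B[d, ]), 0.05)
  if (random_var) {
    B[3, 1] <- ar[1]; B[4, 1] <- ar[2]; B[5, 1] <- cr[1]; B[6, 1] <- cr[2]
    delta2[3:6] <- 0.02
  }
  phi <- matrix(rep(c(ar, cr), each = nrow(Xb)), nrow(Xb))
  # x1 AR(1) moments
  x1 <- rec$x1
  x1prev <- rep(NA_real_, length(x1))
  x1prev[tgt] <- x1[idx$prev[tgt] + 1L]
  okx <- !is.na(x1) & !is.na(x1prev)
  xa <- if (sum(okx) > 5)
    sum(x1[okx] * x1prev[okx]) / max(sum(x1prev[okx]^2), 1e-8) else 0.2
  xa <- max(min(xa, 0.95), -0.95)
  xv <- max(stats::var(x1, na.rm = TRUE) * (1 - xa^2), 0.05)
  list(mu = mu, B = B, delta2 = delta2, ar = ar, cr = cr, cd = cd,
       sigma = c(max(s1, 0.05), max(s2, 0.05), max(min(r0, 0.95), -0.95)),
       phi = phi, x_ar = xa, x_var = xv)
}

run_chains <- function(panel, Xb, random_var, augment, priors, settings,
                       estimate, inits_override = NULL) {
  idx <- build_indices(panel)
  rec <- panel$records
  y <- cbind(rec$y1, rec$y2)
  x <- cbind(rec$x1, rec$x2)
  if (!augment && anyNA(cbind(y, x)))
    stop("fit_mvar requires complete modeled columns; use fit_mvar_bfiml or impute first")
  if (anyNA(x[, 2])) stop("x2 must be fully observed")
  inits <- default_inits(panel, Xb, random_var)
  if (!is.null(inits_override))
    inits <- utils::modifyList(inits, inits_override)
  if (estimate$delta_zero) {
    inits$delta2[1:2] <- 0
    inits$mu <- Xb %*% t(inits$B[1:2, , drop = FALSE])
  }
  ctrl <- list(iterations = settings$adaptation + settings$iterations,
               burn_in = settings$adaptation + settings$burn_in,
               thin = settings$thin,
               est_arcr = estimate$arcr, est_cd = estimate$cd,
               est_sigma = estimate$sigma, est_corr = estimate$corr,
               delta_zero = estimate$delta_zero,
               est_between = estimate$between)
  set.seed(settings$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, settings$chains)
  nm <- param_names_fit(random_var, colnames(Xb), augment)
  draws <- vector("list", settings$chains)
  ymean <- NULL
  x1mean <- NULL
  for (ch in seq_len(settings$chains)) {
    set.seed(chain_seeds[ch])
    ini <- inits
    # overdispersed starts: jitter continuous state per chain
    if (ch > 1) {
      ini$mu <- ini$mu + matrix(stats::rnorm(length(ini$mu), 0, 0.2),
                                nrow(ini$mu))
      ini$sigma[1:2] <- ini$sigma[1:2] * stats::runif(2, 0.7, 1.4)
      if (!estimate$delta_zero)
        ini$delta2 <- ini$delta2 * stats::runif(length(ini$delta2),
                                                0.6, 1.6)
    }
    res <- mvar_gibbs_cpp(y, x, idx$pid, idx$prev, Xb,
                          random_var, augment,
                          unclass(priors), ctrl, ini)
    m <- res$draws
    colnames(m) <- nm
    # derived process-noise covariance
    m <- cbind(m, cov12 = m[, "rho"] *
                 sqrt(m[, "sigma2_1"] * m[, "sigma2_2"]))
    draws[[ch]] <- m
    if (augment) {
      ymean <- if (is.null(ymean)) res$ymean else ymean + res$ymean
      x1mean <- if (is.null(x1mean)) res$x1mean else x1mean + res$x1mean
    }
  }
  if (augment) {
    ymean <- ymean / settings$chains
    x1mean <- x1mean / settings$chains
  }
  structure(list(draws = draws, params = c(nm, "cov12"),
                 settings = settings, random_var = random_var,
                 augment = augment, ymean = ymean, x1mean = x1mean,
                 xb_names = colnames(Xb)),
            class = "posterior_draws")
}

between_design <- function(panel) {
  per <- panel$persons
  cols <- setdiff(names(per), "person_id")
  Xb <- cbind(1, as.matrix(per[cols]))
  colnames(Xb) <- c("(Intercept)", cols)
  if (anyNA(Xb)) stop("person-level covariates must be complete at fit time")
  Xb
}

#' Fit the multilevel VAR(1) model to complete data
#'
#' Bayesian estimation by a bespoke Gibbs-within-slice sampler (see the
#' package vignette for the block structure). The model regresses each
#' person-specific parameter on the person-level covariates; with
#' `spec$random_var_params = FALSE` the AR/CR coefficients are fixed effects
#' shared across persons (the simulation variant), otherwise they are
#' person-specific with their own between-level model (the empirical
#' variant).
#'
#' @param data a complete [panel_data()] (no missing modeled cells).
#' @param spec an [mvar_spec()] skeleton — only `random_var_params` is
#'   consulted, the parameter values are estimated.
#' @param priors a [prior_set()].
#' @param settings an [mcmc_settings()] (at least 2 chains).
#' @param estimate list of update switches, mainly for degenerate-model
#'   checks: `arcr`, `cd`, `sigma`, `corr` (logical; `FALSE` holds the block
#'   at its initial value) and `delta_zero` (fixes both random-intercept
#'   variances at zero).
#' @param inits optional named list overriding the data-derived initial
#'   values (`mu`, `B`, `delta2`, `ar`, `cr`, `cd`, `sigma`, ...).
#' @return A `posterior_draws` object: per-chain matrices of retained draws,
#'   parameter names, and the settings used.
#' @export
fit_mvar <- function(data, spec = mvar_spec(), priors = prior_set(),
                     settings = mcmc_settings_study(),
                     estimate = list(), inits = NULL) {
  est <- utils::modifyList(list(arcr = TRUE, cd = TRUE, sigma = TRUE, between = TRUE,
                                corr = TRUE, delta_zero = FALSE), estimate)
  if (est$delta_zero && spec$random_var_params)
    stop("delta_zero is only supported for the fixed-VAR variant")
  Xb <- between_design(data)
  run_chains(data, Xb, spec$random_var_params, augment = FALSE,
             priors, settings, est, inits)
}

#' Fit the multilevel VAR(1) model with full-information missing-data
#' handling
#'
#' Bayesian full-information treatment: missing dependent-variable cells are
#' sampled as parameters from their full conditionals under the VAR
#' likelihood (with a stationary-law prior for a missing first occasion), and
#' missing `x1` cells are sampled under a declared AR(1) covariate model with
#' weakly informative priors (`x_ar ~ N(0, 1)`, innovation variance uniform
#' on (0, 100)), whose parameters are estimated alongside. `x2` must be fully
#' observed.
#'
#' @inheritParams fit_mvar
#' @param data an [panel_data()] with mask (missingness in `y1`, `y2`, `x1`).
#' @return A `posterior_draws` object (includes `x_ar`, `x_var` columns);
#'   `$ymean` and `$x1mean` hold the posterior means of every cell (observed
#'   cells unchanged, missing cells averaged over their sampled values).
#' @export
fit_mvar_bfiml <- function(data, spec = mvar_spec(), priors = prior_set(),
                           settings = mcmc_settings_study(),
                           estimate = list(), inits = NULL) {
  est <- utils::modifyList(list(arcr = TRUE, cd = TRUE, sigma = TRUE, between = TRUE,
                                corr = TRUE, delta_zero = FALSE), estimate)
  Xb <- between_design(data)
  run_chains(data, Xb, spec$random_var_params, augment = TRUE,
             priors, settings, est, inits)
}

#' Listwise-deletion preparation
#'
#' Drops every occasion with a missing modeled cell and re-links the
#' remaining rows so that each retained row's lag predecessor is the nearest
#' earlier retained row of the same person. This deliberately distorts the
#' true time intervals — the well-known pathology of listwise deletion in
#' lagged models — and is exactly what fitting the VAR to the re-indexed
#' panel does. Persons left with fewer than 2 rows are dropped with a
#' warning.
#'
#' @param data an [panel_data()] with mask.
#' @return A complete [panel_data()] with re-numbered consecutive `t`; the
#'   original occasion indices are kept in `meta$original_t`.
#' @export
listwise_prepare <- function(data) {
  rec <- data$records
  keep <- stats::complete.cases(rec[c("y1", "y2", "x1", "x2")])
  rec <- rec[keep, ]
  cnt <- table(rec$person_id)
  few <- names(cnt)[cnt < 2]
  if (length(few)) {
    warning("listwise deletion dropped ", length(few),
            " person(s) with < 2 remaining rows")
    rec <- rec[!(rec$person_id %in% few), ]
  }
  if (!nrow(rec)) stop("no rows remain after listwise deletion")
  orig_t <- rec$t
  rec$t <- stats::ave(rec$t, rec$person_id, FUN = seq_along)
  persons <- data$persons[data$persons$person_id %in% rec$person_id, ,
                          drop = FALSE]
  meta <- data$meta
  meta$original_t <- orig_t
  meta$listwise <- TRUE
  panel_data(rec, persons, meta = meta)
}
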