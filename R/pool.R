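#' Rubin's rules pooling
#'
#' Pooled point estimate = mean of the per-imputation estimates; total
#' variance = within-imputation variance (mean squared SE) plus
#' `(1 + 1/m)` times the between-imputation variance (unbiased variance of
#' the estimates).
#'
#' @param estimates numeric vector of m per-imputation point estimates.
#' @param ses numeric vector of m per-imputation standard errors.
#' @return list with `estimate` and `se`.
#' @export
pool_rubin <- function(estimates, ses) {
  if (length(estimates) != length(ses))
    stop("estimates and ses must have the same length")
  m <- length(estimates)
  if (m < 2) stop("pooling requires m >= 2")
  qbar <- mean(estimates)
  within <- mean(ses^2)
  between <- stats::var(estimates)
  list(estimate = qbar, se = sqrt(within + (1 + 1 / m) * between))
}

#' Pool posterior draws across imputations by mixing
#'
#' Concatenates the retained draws of the m per-imputation fits into one
#' mixture per parameter and summarises the mixture (mean, SD, 2.5%/97.5%
#' quantiles). This propagates both within- and between-imputation
#' variability directly through the posterior.
#'
#' @param draws_list list of m `posterior_draws` objects over identical
#'   parameter sets.
#' @return data.frame with one row per parameter: `mean`, `sd`, `ci_low`,
#'   `ci_high`.
#' @export
pool_posterior <- function(draws_list) {
  pars <- draws_list[[1]]$params
  for (d in draws_list[-1])
    if (!identical(d$params, pars))
      stop("parameter sets differ across imputations")
  mix <- do.call(rbind, lapply(draws_list,
                               function(d) do.call(rbind, d$draws)))
  data.frame(parameter = pars,
             mean = colMeans(mix),
             sd = apply(mix, 2, stats::sd),
             ci_low = apply(mix, 2, stats::quantile, 0.025),
             ci_high = apply(mix, 2, stats::quantile, 0.975),
             row.names = NULL)
}

#' Monte Carlo evaluation metrics
#'
#' For each parameter, over H Monte Carlo runs:
#' bias `= mean(est - truth)`, relative bias `= mean((est - truth)/truth)`
#' (truth must be nonzero), RMSE `= sqrt(mean((est - truth)^2))`, and the
#' SE-calibration difference `dsd = mean(se) - sd(est)` (average estimated
#' standard error minus the empirical Monte Carlo standard deviation).
#'
#' @param estimates_by_run H x P matrix (runs in rows, parameters in
#'   columns, named).
#' @param ses_by_run H x P matrix of per-run standard errors.
#' @param truth named numeric of true values (names matching columns).
#' @return data.frame of class `metric_report`: per-parameter `bias`,
#'   `relative_bias`, `rmse`, `dsd`, with `H` attached as an attribute.
#' @export
mc_metrics <- function(estimates_by_run, ses_by_run, truth) {
  est <- as.matrix(estimates_by_run)
  ses <- as.matrix(ses_by_run)
  H <- nrow(est)
  if (H < 2) stop("metrics require H >= 2 runs")
  pars <- colnames(est)
  truth <- truth[pars]
  if (any(truth == 0))
    stop("relative bias undefined for zero true values: ",
         paste(pars[truth == 0], collapse = ", "))
  dev <- sweep(est, 2, truth)
  out <- data.frame(
    parameter = pars,
    truth = as.numeric(truth),
    bias = colMeans(dev),
    relative_bias = colMeans(sweep(dev, 2, truth, `/`)),
    rmse = sqrt(colMeans(dev^2)),
    dsd = colMeans(ses) - apply(est, 2, stats::sd),
    row.names = NULL)
  attr(out, "H") <- H
  class(out) <- c("metric_report", class(out))
  out
}

#' Average metrics over declared parameter groups
#'
#' Groups follow the reporting convention for this model class: VAR
#' parameters (AR + CR), random-intercept parameters (between-level fixed
#' effects + random-effect variances), covariate effects, and process-noise
#' variance-covariance parameters; the variance-only subsets `noise_var` and
#' `re_var` are also reported.
#'
#' @param report a [mc_metrics()] data.frame over the standard parameter set.
#' @return data.frame with one row per group, averaging each metric over the
#'   group members present in `report`.
#' @export
group_metrics <- function(report) {
  groups <- param_groups(report$parameter)
  do.call(rbind, lapply(names(groups), function(gn) {
    sel <- report$parameter %in% groups[[gn]]
    if (!any(sel)) return(NULL)
    data.frame(group = gn,
               bias = mean(report$bias[sel]),
               relative_bias = mean(report$relative_bias[sel]),
               rmse = mean(report$rmse[sel]),
               dsd = mean(report$dsd[sel]),
               n_params = sum(sel))
  }))
}

param_groups <- function(all_params) {
  fe <- grep("^b_mu", all_params, value = TRUE)
  list(var_params = c("ar1", "ar2", "cr1", "cr2"),
       random_intercept = c(fe, "delta2_mu1", "delta2_mu2"),
       covs = c("c1", "c2", "d1", "d2"),
       noise_varcov = c("sigma2_1", "sigma2_2", "cov12"),
       noise_var = c("sigma2_1", "sigma2_2"),
       re_var = c("delta2_mu1", "delta2_mu2"))
}

study_truth <- function(spec, icc_target) {
  dm <- solve_re_variance_for_icc(spec, icc_target)
  s <- sqrt(spec$noise_var)
  xn <- colnames(spec$between_B)
  tr <- c(
    stats::setNames(spec$between_B["mu1", ], paste0("b_mu1_", xn)),
    stats::setNames(spec$between_B["mu2", ], paste0("b_mu2_", xn)),
    delta2_mu1 = unname(dm[1]), delta2_mu2 = unname(dm[2]),
    ar1 = spec$ar[1], ar2 = spec$ar[2],
    cr1 = spec$cr[1], cr2 = spec$cr[2],
    c1 = unname(spec$cov_effects["c1"]), c2 = unname(spec$cov_effects["c2"]),
    d1 = unname(spec$cov_effects["d1"]), d2 = unname(spec$cov_effects["d2"]),
    sigma2_1 = spec$noise_var[1], sigma2_2 = spec$noise_var[2],
    rho = spec$noise_corr,
    cov12 = spec$noise_corr * s[1] * s[2])
  tr
}

#' Run the Monte Carlo missing-data study
#'
#' For each design condition and replication: simulate a complete panel,
#' impose calibrated 30% MAR missingness, handle the missingness with each
#' requested method (fit to complete data; single-level or multilevel
#' multiple imputation followed by per-imputation fits and posterior-mixture
#' pooling; Bayesian full-information estimation; listwise deletion), and
#' record the pooled posterior mean and SD per parameter. Metrics are then
#' aggregated per parameter and per reporting group.
#'
#' A failed replication is recorded without aborting; a condition errors if
#' more than 10% of its replications fail.
#'
#' @param conditions data.frame with columns `N`, `T_occasions`,
#'   `icc_target` (one row per condition).
#' @param methods subset of `c("complete", "slmi", "mlmi", "bfiml", "ld")`.
#' @param H number of Monte Carlo replications per condition (the reference
#'   protocol uses 100).
#' @param seed root seed; every per-replication stage seed derives from it
#'   and is logged in the result.
#' @param spec generating [mvar_spec()] (true parameter values).
#' @param m,sweeps imputation settings (defaults 5 and 10).
#' @param target_rate,mar_slope amputation calibration target and logit
#'   slope on `x2` (defaults 0.30 and 0.5).
#' @param settings_fn function(seed) returning the [mcmc_settings()] used
#'   for each fit; defaults to the desk-scale study settings.
#' @param progress logical; print one line per replication.
#' @return list of per-condition results, each with `metrics` (per
#'   parameter, per method), `group_metrics`, `estimates`/`ses` matrices,
#'   `truth`, `seeds` and `failures`.
#' @export
run_study <- function(conditions = data.frame(N = 100, T_occasions = 100,
                                              icc_target = 0.5),
                      methods = c("complete", "slmi", "mlmi", "bfiml", "ld"),
                      H = 100, seed = 1L, spec = mvar_spec(),
                      m = 5, sweeps = 10,
                      target_rate = 0.30, mar_slope = 0.5,
                      settings_fn = function(s) mcmc_settings_study(seed = s),
                      progress = FALSE) {
  methods <- match.arg(methods, c("complete", "slmi", "mlmi", "bfiml", "ld"),
                       several.ok = TRUE)
  set.seed(seed)
  all_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 nrow(conditions) * H * 8),
                      ncol = 8)
  out <- vector("list", nrow(conditions))
  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions[ci, ]
    truth <- study_truth(spec, cond$icc_target)
    pars <- setdiff(names(truth), "rho")
    est <- ses <- list()
    for (meth in methods) {
      est[[meth]] <- matrix(NA_real_, H, length(pars),
                            dimnames = list(NULL, pars))
      ses[[meth]] <- est[[meth]]
    }
    failures <- character()
    for (h in seq_len(H)) {
      sd_row <- all_seeds[(ci - 1) * H + h, ]
      res <- tryCatch(
        study_replication(cond, spec, methods, sd_row, m, sweeps,
                          target_rate, mar_slope, settings_fn),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures <- c(failures, paste0("rep ", h, ": ",
                                       conditionMessage(res)))
        next
      }
      for (meth in names(res)) {
        est[[meth]][h, ] <- res[[meth]]$mean[pars]
        ses[[meth]][h, ] <- res[[meth]]$sd[pars]
      }
      if (progress)
        message("condition ", ci, " replication ", h, " done")
    }
    if (length(failures) > 0.1 * H)
      stop("condition ", ci, ": more than 10% of replications failed:\n",
           paste(failures, collapse = "\n"))
    okrows <- stats::complete.cases(est[[methods[1]]])
    metric_tabs <- lapply(methods, function(meth) {
      mr <- mc_metrics(est[[meth]][okrows, , drop = FALSE],
                       ses[[meth]][okrows, , drop = FALSE], truth)
      mr$method <- meth
      mr
    })
    names(metric_tabs) <- methods
    gm <- do.call(rbind, lapply(methods, function(meth) {
      g <- group_metrics(metric_tabs[[meth]])
      g$method <- meth
      g
    }))
    out[[ci]] <- list(condition = cond,
                      metrics = do.call(rbind, metric_tabs),
                      group_metrics = gm,
                      estimates = est, ses = ses, truth = truth,
                      seeds = all_seeds[(ci - 1) * H + seq_len(H), ,
                                        drop = FALSE],
                      failures = failures)
  }
  out
}

study_replication <- function(cond, spec, methods, sd_row, m, sweeps,
                              target_rate, mar_slope, settings_fn) {
  design <- sim_design(N = cond$N, T_occasions = cond$T_occasions,
                       icc_target = cond$icc_target, seed = sd_row[1])
  panel <- simulate_panel(design, spec)
  psi0 <- calibrate_intercept(panel, mar_slope, target_rate)
  mm <- missingness_model(psi0_dv = psi0, psi1 = mar_slope,
                          psi0_x1 = psi0, psi_x2 = mar_slope)
  panel_mar <- apply_mar(panel, mm, seed = sd_row[2])
  fit_spec <- mvar_spec(random_var_params = FALSE)
  res <- list()
  summ_of <- function(pd) {
    s <- summarize_draws(pd)
    list(mean = stats::setNames(s$mean, s$parameter),
         sd = stats::setNames(s$sd, s$parameter))
  }
  pool_of <- function(completed, seed0) {
    fits <- lapply(seq_along(completed$panels), function(k)
      fit_mvar(completed$panels[[k]], fit_spec,
               settings = settings_fn(seed0 + k)))
    s <- pool_posterior(fits)
    list(mean = stats::setNames(s$mean, s$parameter),
         sd = stats::setNames(s$sd, s$parameter))
  }
  if ("complete" %in% methods)
    res$complete <- summ_of(fit_mvar(panel, fit_spec,
                                     settings = settings_fn(sd_row[3])))
  if ("slmi" %in% methods) {
    cfg <- imputation_config(m = m, sweeps = sweeps,
                             method = "single_level", seed = sd_row[4])
    res$slmi <- pool_of(average_person_level(impute_panel(panel_mar, cfg)),
                        sd_row[5])
  }
  if ("mlmi" %in% methods) {
    cfg <- imputation_config(m = m, sweeps = sweeps,
                             method = "multilevel", seed = sd_row[6])
    res$mlmi <- pool_of(impute_panel(panel_mar, cfg), sd_row[7])
  }
  if ("bfiml" %in% methods)
    res$bfiml <- summ_of(fit_mvar_bfiml(panel_mar, fit_spec,
                                        settings = settings_fn(sd_row[8])))
  if ("ld" %in% methods) {
    ldp <- suppressWarnings(listwise_prepare(panel_mar))
    res$ld <- summ_of(fit_mvar(ldp, fit_spec,
                               settings = settings_fn(sd_row[3] + 1)))
  }
  res
}
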