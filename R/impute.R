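#' Configuration for chained-equations multiple imputation
#'
#' @param m number of completed data sets (>= 2); the study default is 5.
#' @param sweeps chained-equation cycles per completed set (>= 1; default 10,
#'   a common burn-in for fully conditional specification).
#' @param method `"multilevel"` (random-intercept imputation models) or
#'   `"single_level"` (multilevel structure ignored).
#' @param seed integer seed; all m sets derive sub-seeds from it.
#' @param pmm logical; `TRUE` replaces posterior-predictive draws with
#'   predictive-mean matching (nearest observed donor). Default `FALSE`:
#'   the variables here are continuous and the normal draw is the primary
#'   method.
#' @return Object of class `imputation_config`.
#' @export
imputation_config <- function(m = 5, sweeps = 10,
                              method = c("multilevel", "single_level"),
                              seed = 1L, pmm = FALSE) {
  stopifnot(m >= 2, sweeps >= 1)
  method <- match.arg(method)
  structure(list(m = as.integer(m), sweeps = as.integer(sweeps),
                 method = method, seed = as.integer(seed), pmm = isTRUE(pmm)),
            class = "imputation_config")
}

#' Build the imputation frame
#'
#' Assembles one row per person-time with the dependent variables, their
#' within-person lag-1 values, the time-varying covariates, the person-level
#' covariates, any auxiliary columns (optionally with their lags), and 0/1
#' missingness-indicator columns mirroring the mask. The lag cells at `t = 1`
#' are missing by construction and never imputed: model fitting consumes
#' `t >= 2` rows, and `t = 1` cells are imputed from a lag-free model.
#'
#' @param panel an [panel_data()] with mask.
#' @param auxiliaries optional data.frame keyed by `(person_id, t)` with
#'   auxiliary columns (e.g. self-initiated-prompt composites).
#' @param aux_lag logical; add within-person lag-1 columns of the auxiliaries.
#' @param use_lags logical; include the lagged-DV columns (default `TRUE`).
#' @param indicators logical; include the missingness-indicator columns.
#' @return A data.frame with attributes `panel`, `lag_map`, `person_cols`,
#'   `indicator_cols`.
#' @export
build_frame <- function(panel, auxiliaries = NULL, aux_lag = TRUE,
                        use_lags = TRUE, indicators = TRUE) {
  rec <- panel$records
  fr <- rec[c("person_id", "t", "y1", "y2", "x1", "x2")]
  lag_map <- character()
  if (use_lags) {
    fr$y1_lag <- lag_by_person(rec$y1, rec$person_id)
    fr$y2_lag <- lag_by_person(rec$y2, rec$person_id)
    lag_map <- c(y1_lag = "y1", y2_lag = "y2")
  }
  person_cols <- setdiff(names(panel$persons), "person_id")
  fr <- merge(fr, panel$persons, by = "person_id", sort = FALSE)
  fr <- fr[order(fr$person_id, fr$t), ]
  if (!is.null(auxiliaries)) {
    aux_cols <- setdiff(names(auxiliaries), c("person_id", "t"))
    fr <- merge(fr, auxiliaries, by = c("person_id", "t"),
                all.x = TRUE, sort = FALSE)
    fr <- fr[order(fr$person_id, fr$t), ]
    if (aux_lag) {
      for (a in aux_cols) {
        nm <- paste0(a, "_lag")
        fr[[nm]] <- lag_by_person(fr[[a]], fr$person_id)
        lag_map <- c(lag_map, stats::setNames(a, nm))
      }
    }
  }
  ind_cols <- character()
  if (indicators) {
    fr$r_y1 <- panel$mask$y1
    fr$r_y2 <- panel$mask$y2
    fr$r_x1 <- panel$mask$x1
    ind_cols <- c("r_y1", "r_y2", "r_x1")
  }
  rownames(fr) <- NULL
  attr(fr, "panel") <- panel
  attr(fr, "lag_map") <- lag_map
  attr(fr, "person_cols") <- person_cols
  attr(fr, "indicator_cols") <- ind_cols
  fr
}

lag_by_person <- function(x, person_id) {
  out <- c(NA, x[-length(x)])
  out[c(TRUE, person_id[-1] != person_id[-length(person_id)])] <- NA
  out
}

# proper Bayesian draw from a normal linear model (noninformative prior),
# returning imputations for rows Xmis; ridge stabilises near-collinearity
norm_draw <- function(y, X, Xmis, pmm = FALSE) {
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  keep[1] <- TRUE  # intercept
  X <- X[, keep, drop = FALSE]
  Xmis <- Xmis[, keep, drop = FALSE]
  n <- length(y); p <- ncol(X)
  XtX <- crossprod(X)
  XtX <- XtX + diag(1e-5 * mean(diag(XtX)) + 1e-8, p)
  Xty <- crossprod(X, y)
  R <- chol(XtX)
  betahat <- backsolve(R, backsolve(R, Xty, transpose = TRUE))
  ssr <- sum((y - X %*% betahat)^2)
  df <- max(n - p, 1)
  sigma2 <- ssr / stats::rchisq(1, df)
  beta <- betahat + sqrt(sigma2) * backsolve(R, stats::rnorm(p))
  pred <- drop(Xmis %*% beta)
  if (pmm) {
    fitted_obs <- drop(X %*% beta)
    idx <- vapply(pred, function(v) which.min(abs(fitted_obs - v)), 1L)
    y[idx]
  } else {
    pred + sqrt(sigma2) * stats::rnorm(length(pred))
  }
}

# one Gibbs refresh + predictive draw for the two-level normal model with a
# person random intercept (Kasim-Raudenbush style); state carries across
# sweeps for mixing
twolevel_draw <- function(y, X, g, Xmis, gmis, ngroups, state = NULL,
                          scans = 5) {
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  keep[1] <- TRUE
  X <- X[, keep, drop = FALSE]
  Xmis <- Xmis[, keep, drop = FALSE]
  n <- length(y); p <- ncol(X)
  XtX <- crossprod(X)
  XtX <- XtX + diag(1e-5 * mean(diag(XtX)) + 1e-8, p)
  R <- chol(XtX)
  if (is.null(state)) {
    betahat <- backsolve(R, backsolve(R, crossprod(X, y), transpose = TRUE))
    res <- y - drop(X %*% betahat)
    gm <- tapply(res, factor(g, levels = seq_len(ngroups)), mean)
    gm[is.na(gm)] <- 0
    state <- list(beta = betahat, b = as.numeric(gm),
                  s2w = max(stats::var(res), 1e-8),
                  s2b = max(stats::var(as.numeric(gm)), 1e-8))
  }
  ni <- tabulate(g, nbins = ngroups)
  for (s in seq_len(scans)) {
    # beta | b, s2w
    yt <- y - state$b[g]
    betahat <- backsolve(R, backsolve(R, crossprod(X, yt), transpose = TRUE))
    state$beta <- betahat +
      sqrt(state$s2w) * backsolve(R, stats::rnorm(p))
    # b_i | beta, s2w, s2b  (conjugate, vectorised over persons)
    res <- y - drop(X %*% state$beta)
    sums <- rowsum_groups(res, g, ngroups)
    prec <- ni / state$s2w + 1 / state$s2b
    mu_b <- (sums / state$s2w) / prec
    state$b <- mu_b + stats::rnorm(ngroups) / sqrt(prec)
    # s2w | beta, b (flat prior on the variance)
    ssr <- sum((res - state$b[g])^2)
    state$s2w <- ssr / stats::rchisq(1, max(n - p, 1))
    # s2b | b
    ssb <- sum(state$b^2)
    state$s2b <- max(ssb / stats::rchisq(1, max(ngroups - 2, 1)), 1e-10)
  }
  pred <- drop(Xmis %*% state$beta) + state$b[gmis]
  list(imp = pred + sqrt(state$s2w) * stats::rnorm(length(pred)),
       state = state)
}

rowsum_groups <- function(x, g, ngroups) {
  out <- numeric(ngroups)
  rs <- rowsum(x, g)
  out[as.integer(rownames(rs))] <- rs
  out
}

#' Single-level chained-equations imputation
#'
#' Fully conditional specification ignoring the multilevel structure: each
#' incomplete column is imputed from a proper Bayesian normal linear model
#' (parameters drawn from their posterior under a noninformative prior given
#' the current completed data, then missing cells drawn from the posterior
#' predictive). Columns are visited in ascending order of missingness
#' fraction (ties by name) each sweep; lag columns are passively recomputed
#' from the current completed values at the start of every sweep. The whole
#' cycle is repeated from `m` distinct sub-seeds.
#'
#' @param frame a [build_frame()] output.
#' @param config an [imputation_config()] with `method = "single_level"`.
#' @return A `completed_set`: `m` completed panels plus provenance.
#' @export
impute_single_level <- function(frame, config) {
  if (config$method != "single_level")
    stop("config$method must be 'single_level'")
  fcs_run(frame, config, multilevel = FALSE)
}

#' Multilevel chained-equations imputation
#'
#' As [impute_single_level()], except each incomplete level-1 column is
#' imputed from a two-level normal model with a person random intercept
#' (Gibbs draws of fixed effects, person intercepts and variance components
#' given the current completed data, then posterior-predictive draws), so
#' between-person heterogeneity is preserved in the imputations. Incomplete
#' person-level covariates are imputed at the person level — one value per
#' person per completed set.
#'
#' @inheritParams impute_single_level
#' @return A `completed_set`.
#' @export
impute_multilevel <- function(frame, config) {
  if (config$method != "multilevel")
    stop("config$method must be 'multilevel'")
  panel <- attr(frame, "panel")
  if (n_persons(panel) < 2) stop("multilevel imputation needs >= 2 persons")
  fcs_run(frame, config, multilevel = TRUE)
}

fcs_run <- function(frame, config, multilevel) {
  panel <- attr(frame, "panel")
  lag_map <- attr(frame, "lag_map")
  person_cols <- attr(frame, "person_cols")
  ind_cols <- attr(frame, "indicator_cols")
  id_cols <- c("person_id", "t")
  lag_cols <- names(lag_map)
  # imputable targets: any column (level-1 or person-level) with missing
  # cells, excluding passive lags, ids, indicators
  cand <- setdiff(names(frame), c(id_cols, lag_cols, ind_cols))
  targets <- cand[vapply(cand, function(cl) anyNA(frame[[cl]]), TRUE)]
  for (cl in targets) {
    if (all(is.na(frame[[cl]])))
      stop("column with zero observed cells: ", cl)
  }
  # visit order: ascending missingness fraction, ties by name
  frac <- vapply(targets, function(cl) mean(is.na(frame[[cl]])), 0)
  targets <- targets[order(frac, targets)]
  l2_targets <- intersect(targets, person_cols)
  l1_targets <- setdiff(targets, l2_targets)
  miss_idx <- lapply(stats::setNames(targets, targets),
                     function(cl) which(is.na(frame[[cl]])))

  g <- match(frame$person_id, panel$persons$person_id)
  ngroups <- nrow(panel$persons)
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, config$m)
  completed_panels <- vector("list", config$m)
  person_miss <- lapply(stats::setNames(l2_targets, l2_targets),
                        function(cl) {
                          pm <- panel$persons[[cl]]
                          which(is.na(pm))
                        })

  for (k in seq_len(config$m)) {
    set.seed(sub_seeds[k])
    cur <- frame
    # initial fill: random draws from the observed cells of each column
    for (cl in targets) {
      obs <- cur[[cl]][!is.na(cur[[cl]])]
      cur[[cl]][miss_idx[[cl]]] <- sample(obs, length(miss_idx[[cl]]),
                                          replace = TRUE)
    }
    st_env <- new.env(parent = emptyenv())
    st_env$state <- list()
    for (sw in seq_len(config$sweeps)) {
      # passive lag refresh
      for (lc in lag_cols)
        cur[[lc]] <- lag_by_person(cur[[lag_map[lc]]], cur$person_id)
      for (cl in l1_targets) {
        mi <- miss_idx[[cl]]
        if (!length(mi)) next
        preds <- setdiff(names(cur), c(id_cols, cl,
                                       indicator_of(cl, ind_cols)))
        # rows with complete lag predictors (t >= 2 within person)
        lagged_preds <- intersect(preds, lag_cols)
        ok_lag <- if (length(lagged_preds))
          !Reduce(`|`, lapply(cur[lagged_preds], is.na)) else
            rep(TRUE, nrow(cur))
        is_mi <- logical(nrow(cur)); is_mi[mi] <- TRUE
        fit_rows <- which(ok_lag & !is_mi)
        imp_rows <- mi[ok_lag[mi]]
        cur <- impute_column(cur, cl, preds, fit_rows, imp_rows,
                             g, ngroups, multilevel, config$pmm,
                             st_env, cl)
        # t = 1 (structurally missing lags): lag-free model
        rest <- mi[!ok_lag[mi]]
        if (length(rest)) {
          preds0 <- setdiff(preds, lag_cols)
          fit0 <- which(!is_mi)
          cur <- impute_column(cur, cl, preds0, fit0, rest, g, ngroups,
                               multilevel, config$pmm, st_env,
                               paste0(cl, ".nolag"))
        }
      }
      # person-level targets: one value per person, person-level regression
      for (cl in l2_targets) {
        pm <- person_miss[[cl]]
        if (!length(pm)) next
        cur <- impute_person_level(cur, cl, pm, panel, person_cols,
                                   id_cols, ind_cols, multilevel)
      }
    }
    # final passive refresh so emitted lags match completed DVs exactly
    for (lc in lag_cols)
      cur[[lc]] <- lag_by_person(cur[[lag_map[lc]]], cur$person_id)
    completed_panels[[k]] <- frame_to_panel(cur, panel, person_cols, k,
                                            config)
  }
  structure(list(panels = completed_panels,
                 method = if (multilevel) "multilevel" else "single_level",
                 m = config$m, sweeps = config$sweeps, seed = config$seed,
                 person_miss = person_miss,
                 source = panel),
            class = "completed_set")
}

# indicator column of a target is excluded from its own predictor set
indicator_of <- function(cl, ind_cols) {
  nm <- paste0("r_", cl)
  intersect(nm, ind_cols)
}

impute_column <- function(cur, cl, preds, fit_rows, imp_rows, g, ngroups,
                          multilevel, pmm, st_env, state_key) {
  if (!length(imp_rows)) return(cur)
  if (length(fit_rows) < 5) {
    # too few complete cases for a regression: hot-deck from observed cells
    obs <- cur[[cl]][fit_rows]
    if (!length(obs)) obs <- cur[[cl]][-imp_rows]
    cur[[cl]][imp_rows] <- sample(obs, length(imp_rows), replace = TRUE)
    return(cur)
  }
  X <- cbind(1, as.matrix(cur[fit_rows, preds, drop = FALSE]))
  Xm <- cbind(1, as.matrix(cur[imp_rows, preds, drop = FALSE]))
  y <- cur[[cl]][fit_rows]
  if (multilevel) {
    res <- twolevel_draw(y, X, g[fit_rows], Xm, g[imp_rows], ngroups,
                         st_env$state[[state_key]])
    st_env$state[[state_key]] <- res$state
    cur[[cl]][imp_rows] <- res$imp
  } else {
    cur[[cl]][imp_rows] <- norm_draw(y, X, Xm, pmm = pmm)
  }
  cur
}

impute_person_level <- function(cur, cl, pm_idx, panel, person_cols,
                                id_cols, ind_cols, multilevel) {
  # person-level regression: target on other person covariates + person
  # means of the level-1 columns
  l1 <- setdiff(names(cur), c(id_cols, person_cols, ind_cols))
  pmeans <- stats::aggregate(cur[l1], by = list(person_id = cur$person_id),
                             FUN = function(v) mean(v, na.rm = TRUE))
  pdat <- merge(unique(cur[c("person_id", person_cols)]), pmeans,
                by = "person_id", sort = TRUE)
  preds <- setdiff(names(pdat), c("person_id", cl))
  obs <- which(!(seq_len(nrow(pdat)) %in% pm_idx))
  X <- cbind(1, as.matrix(pdat[obs, preds, drop = FALSE]))
  Xm <- cbind(1, as.matrix(pdat[pm_idx, preds, drop = FALSE]))
  imp <- norm_draw(pdat[[cl]][obs], X, Xm)
  for (j in seq_along(pm_idx)) {
    pid <- pdat$person_id[pm_idx[j]]
    cur[[cl]][cur$person_id == pid] <- imp[j]
  }
  cur
}

frame_to_panel <- function(cur, panel, person_cols, k, config) {
  rec <- panel$records
  rec$y1 <- cur$y1
  rec$y2 <- cur$y2
  rec$x1 <- cur$x1
  rec$x2 <- cur$x2
  persons <- panel$persons
  for (pc in person_cols) {
    v <- cur[[pc]][!duplicated(cur$person_id)]
    persons[[pc]] <- v[match(persons$person_id,
                             cur$person_id[!duplicated(cur$person_id)])]
  }
  meta <- panel$meta
  meta$imputation <- list(method = config$method, m = config$m,
                          sweeps = config$sweeps, set = k,
                          seed = config$seed)
  panel_data(rec, persons, meta = meta)
}

#' Average person-level imputations across completed sets
#'
#' After single-level imputation, each completed set carries its own imputed
#' value for an incomplete time-invariant covariate; this replaces every
#' imputed person-level value by its across-set average in all `m` sets
#' (dummy-coded covariates may therefore become non-integer). Level-1 cells
#' are untouched; with no person-level missingness this is the identity.
#'
#' @param completed a `completed_set`.
#' @return The modified `completed_set`.
#' @export
average_person_level <- function(completed) {
  pm <- completed$person_miss
  if (!length(pm)) return(completed)
  for (cl in names(pm)) {
    idx <- pm[[cl]]
    if (!length(idx)) next
    vals <- sapply(completed$panels, function(p) p$persons[[cl]][idx])
    avg <- if (length(idx) == 1) mean(vals) else rowMeans(vals)
    for (k in seq_along(completed$panels))
      completed$panels[[k]]$persons[[cl]][idx] <- avg
  }
  completed
}

#' One-call imputation of a panel
#'
#' Convenience wrapper: builds the frame and dispatches on `config$method`.
#'
#' @param panel an [panel_data()] with mask.
#' @param config an [imputation_config()].
#' @param auxiliaries optional auxiliary data.frame (see [build_frame()]).
#' @param ... passed to [build_frame()].
#' @return A `completed_set`.
#' @export
impute_panel <- function(panel, config, auxiliaries = NULL, ...) {
  fr <- build_frame(panel, auxiliaries = auxiliaries, ...)
  if (config$method == "multilevel") impute_multilevel(fr, config)
  else impute_single_level(fr, config)
}

#' @export
print.completed_set <- function(x, ...) {
  cat("completed_set: m =", x$m, "sets,", x$method,
      "imputation,", x$sweeps, "sweeps\n")
  invisible(x)
}
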