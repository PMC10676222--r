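#' Long-format multi-subject panel with an aligned missingness mask
#'
#' The central data container: a long table of person-time records for the two
#' dependent variables and the two time-varying covariates, a person-level
#' table of time-invariant covariates, and a 0/1 missingness mask aligned with
#' the `(y1, y2, x1)` cells (the only cells the workbench ever amputates or
#' imputes; `x2` and the person-level covariates stay complete in the
#' simulation design).
#'
#' @param records data.frame with columns `person_id`, `t`, `y1`, `y2`, `x1`,
#'   `x2`; within each person `t` must run `1..T_i` consecutively. Missing
#'   cells are `NA`.
#' @param persons data.frame with column `person_id` and time-invariant
#'   covariates (at least `x3` for simulated panels).
#' @param mask optional data.frame/matrix with columns `y1`, `y2`, `x1` of
#'   0/1 indicators, one row per record; derived from the `NA` pattern when
#'   omitted.
#' @param meta list of provenance fields (e.g. `seed`, `tag`).
#' @return An object of class `mvar_panel`.
#' @export
panel_data <- function(records, persons, mask = NULL, meta = list()) {
  records <- as.data.frame(records)
  persons <- as.data.frame(persons)
  if (is.null(mask)) {
    mask <- data.frame(y1 = as.integer(is.na(records$y1)),
                       y2 = as.integer(is.na(records$y2)),
                       x1 = as.integer(is.na(records$x1)))
  } else {
    mask <- as.data.frame(mask)[, c("y1", "y2", "x1")]
    mask[] <- lapply(mask, as.integer)
  }
  obj <- structure(list(records = records, persons = persons, mask = mask,
                        meta = meta),
                   class = "mvar_panel")
  viol <- validate_panel(obj)
  if (length(viol)) stop("invalid panel: ", paste(viol, collapse = "; "))
  obj
}

#' Validate an `mvar_panel`
#'
#' @param panel an [panel_data()] object.
#' @return Character vector of violations (empty when valid).
#' @export
validate_panel <- function(panel) {
  out <- character()
  rec <- panel$records
  need <- c("person_id", "t", "y1", "y2", "x1", "x2")
  if (!all(need %in% names(rec)))
    return(paste("records missing columns:",
                 paste(setdiff(need, names(rec)), collapse = ", ")))
  if (nrow(rec) == 0) return("panel has no records")
  for (pid in unique(rec$person_id)) {
    tt <- rec$t[rec$person_id == pid]
    if (!identical(as.integer(tt), seq_len(length(tt))))
      out <- c(out, paste0("person ", pid, ": t not consecutive from 1"))
  }
  if (nrow(panel$mask) != nrow(rec))
    out <- c(out, "mask row count does not match records")
  else {
    for (col in c("y1", "y2", "x1")) {
      if (!identical(as.integer(is.na(rec[[col]])),
                     as.integer(panel$mask[[col]])))
        out <- c(out, paste0("mask misaligned with NA pattern in ", col))
    }
  }
  vals <- unlist(rec[c("y1", "y2", "x1", "x2")], use.names = FALSE)
  if (any(!is.finite(vals[!is.na(vals)])))
    out <- c(out, "non-finite observed value")
  if (!all(unique(rec$person_id) %in% panel$persons$person_id))
    out <- c(out, "records contain person_id absent from persons table")
  out
}

#' Number of persons / records in a panel
#' @param panel an `mvar_panel`.
#' @return Integer count.
#' @export
n_persons <- function(panel) length(unique(panel$records$person_id))

#' @rdname n_persons
#' @export
n_records <- function(panel) nrow(panel$records)

#' @export
print.mvar_panel <- function(x, ...) {
  miss <- colMeans(x$mask)
  cat("mvar_panel: ", n_persons(x), " persons, ", n_records(x),
      " person-time records\n", sep = "")
  cat(sprintf("  missing: y1 %.1f%%, y2 %.1f%%, x1 %.1f%%\n",
              100 * miss[1], 100 * miss[2], 100 * miss[3]))
  if (!is.null(x$meta$seed)) cat("  seed:", x$meta$seed, "\n")
  invisible(x)
}

#' @export
as.data.frame.mvar_panel <- function(x, ...) {
  merge(x$records, x$persons, by = "person_id", sort = FALSE)
}

#' MAR amputation model on the logit scale
#'
#' Parameters of the logistic missingness mechanism: the two dependent
#' variables are jointly set missing with probability
#' `plogis(psi0_dv + psi1 * x2)` and the first time-varying covariate
#' independently with probability `plogis(psi0_x1 + psi_x2 * x2)`. Missingness
#' depends on the always-observed covariate `x2` only, so the mechanism is
#' missing-at-random given the observed data.
#'
#' @param psi0_dv,psi1 intercept and slope for the joint DV indicator.
#' @param psi0_x1,psi_x2 intercept and slope for the `x1` indicator.
#' @return Object of class `missingness_model`.
#' @export
missingness_model <- function(psi0_dv, psi1 = 0.5, psi0_x1 = psi0_dv,
                              psi_x2 = 0.5) {
  stopifnot(is.finite(psi0_dv), is.finite(psi1), is.finite(psi0_x1),
            is.finite(psi_x2))
  structure(list(psi0_dv = psi0_dv, psi1 = psi1,
                 psi0_x1 = psi0_x1, psi_x2 = psi_x2),
            class = "missingness_model")
}
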