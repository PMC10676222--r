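#' Write / read a panel through the CSV dialect
#'
#' A panel round-trips losslessly (including the mask) through three plain
#' text files: `<path>` — the long records CSV (`person_id, t, y1, y2, x1,
#' x2`, missing cells as empty fields, floats at full precision);
#' `<path>.persons.csv` — the person-level covariates; `<path>.manifest` —
#' a plain-text manifest recording the seed and a hash of the content.
#'
#' @param panel an [panel_data()].
#' @param path records CSV path; the two sidecar files derive from it.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  rec <- panel$records
  fmt <- function(df) {
    out <- df
    for (j in seq_along(out))
      if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
    out[is.na(df)] <- ""
    out
  }
  utils::write.csv(fmt(rec), path, row.names = FALSE, quote = FALSE)
  utils::write.csv(fmt(panel$persons), persons_path(path),
                   row.names = FALSE, quote = FALSE)
  manifest <- c(
    paste0("seed: ", if (is.null(panel$meta$seed)) "NA" else panel$meta$seed),
    paste0("tag: ", if (is.null(panel$meta$tag)) "" else panel$meta$tag),
    paste0("records: ", nrow(rec)),
    paste0("persons: ", nrow(panel$persons)),
    paste0("hash: ", content_hash(rec)))
  writeLines(manifest, manifest_path(path))
  invisible(path)
}

persons_path <- function(path) paste0(path, ".persons.csv")
manifest_path <- function(path) paste0(path, ".manifest")

# small deterministic content hash (sum-based; no external digest dep)
content_hash <- function(df) {
  v <- unlist(lapply(df, function(x) {
    if (is.numeric(x)) round(x, 10) else as.character(x)
  }), use.names = FALSE)
  s <- sum(utf8ToInt(paste(head(v, 5000), collapse = ",")) *
             (seq_along(utf8ToInt(paste(head(v, 5000), collapse = ","))) %%
                97 + 1))
  sprintf("%x", s %% 2^31)
}

#' @rdname write_panel
#' @param meta optional list merged into the panel meta on read.
#' @return `read_panel` returns the reconstructed [panel_data()].
#' @export
read_panel <- function(path, meta = list()) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(rec) == 0) stop("empty panel file: ", path)
  need <- c("person_id", "t", "y1", "y2", "x1", "x2")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    stop("malformed panel file ", path, ": missing columns ",
         paste(miss, collapse = ", "))
  persons <- utils::read.csv(persons_path(path), stringsAsFactors = FALSE)
  if (file.exists(manifest_path(path))) {
    mlines <- readLines(manifest_path(path))
    sd <- sub("^seed: ", "", grep("^seed: ", mlines, value = TRUE))
    if (length(sd) && sd != "NA") meta$seed <- as.integer(sd)
  }
  panel_data(rec, persons, meta = meta)
}

#' Write / read posterior draws through a columnar text file
#'
#' Long-format CSV with columns `parameter, chain, iteration, value`
#' (full-precision floats); round-trips a `posterior_draws` object.
#'
#' @param draws a `posterior_draws`.
#' @param path CSV path.
#' @return `path` invisibly; `read_draws` returns the `posterior_draws`.
#' @export
write_draws <- function(draws, path) {
  tabs <- lapply(seq_along(draws$draws), function(ch) {
    m <- draws$draws[[ch]]
    data.frame(parameter = rep(colnames(m), each = nrow(m)),
               chain = ch,
               iteration = rep(seq_len(nrow(m)), ncol(m)),
               value = sprintf("%.17g", as.vector(m)))
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_draws
#' @export
read_draws <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("parameter", "chain", "iteration", "value")
  if (!all(need %in% names(d)))
    stop("malformed draws file: needs columns ",
         paste(need, collapse = ", "))
  pars <- unique(d$parameter)
  chains <- sort(unique(d$chain))
  mats <- lapply(chains, function(ch) {
    dd <- d[d$chain == ch, ]
    m <- matrix(NA_real_, max(dd$iteration), length(pars),
                dimnames = list(NULL, pars))
    for (pn in pars)
      m[, pn] <- dd$value[dd$parameter == pn][order(
        dd$iteration[dd$parameter == pn])]
    m
  })
  structure(list(draws = mats, params = pars, settings = NULL,
                 random_var = NA, augment = NA, xb_names = NULL),
            class = "posterior_draws")
}

#' Derive per-stage seeds from one root seed
#'
#' All randomness in a configured pipeline flows from a single root seed:
#' each named stage receives a reproducible sub-seed drawn from the root
#' stream.
#'
#' @param root_seed integer.
#' @param stages character vector of stage names.
#' @return named integer vector of sub-seeds.
#' @export
derive_seeds <- function(root_seed, stages) {
  set.seed(as.integer(root_seed))
  stats::setNames(sample.int(.Machine$integer.max - 1L, length(stages)),
                  stages)
}

#' Execute a configured pipeline
#'
#' Runs the stages declared in a YAML config in the fixed order
#' simulate -> amputate -> impute -> fit -> pool/metrics (any prefix of that
#' order is allowed). Every stage writes its artifact plus a manifest under
#' `out_dir`; a rerun with the same config reproduces the same files.
#'
#' Config schema (YAML): `seed` (root seed), `out_dir`, `stages` (list of
#' stage names), `design` (`N`, `T_occasions`, `icc_target`), `spec`
#' (optional overrides of [mvar_spec()] arguments), `amputate`
#' (`target_rate`, `slope`), `impute` (`method`, `m`, `sweeps`), `fit`
#' (`variant`: `complete|bfiml|ld`, `chains`, `iterations`, `burn_in`,
#' `adaptation`, `thin`).
#'
#' @param config path to a YAML config file, or an equivalent list.
#' @param out_dir overrides the config's output directory.
#' @return list of produced artifact paths, invisibly.
#' @export
run_config <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  for (f in c("seed", "stages", "out_dir"))
    if (is.null(cfg[[f]]) && !(f == "out_dir" && !is.null(out_dir)))
      stop("config schema violation: missing field '", f, "'")
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  allowed <- c("simulate", "amputate", "impute", "fit")
  stages <- unlist(cfg$stages)
  if (!all(stages %in% allowed))
    stop("config schema violation: unknown stage(s) ",
         paste(setdiff(stages, allowed), collapse = ", "))
  if (!identical(stages, allowed[seq_along(stages)]))
    stop("config schema violation: stages must be a prefix of ",
         paste(allowed, collapse = " -> "))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(cfg$seed, allowed)
  spec <- do.call(mvar_spec, if (is.null(cfg$spec)) list() else cfg$spec)
  paths <- list()
  panel <- NULL
  if ("simulate" %in% stages) {
    dcfg <- cfg$design
    design <- sim_design(N = dcfg$N, T_occasions = dcfg$T_occasions,
                         icc_target = if (is.null(dcfg$icc_target)) 0.5
                                      else dcfg$icc_target,
                         seed = seeds[["simulate"]])
    panel <- simulate_panel(design, spec)
    paths$panel <- file.path(cfg$out_dir, "panel.csv")
    write_panel(panel, paths$panel)
  }
  if ("amputate" %in% stages) {
    acfg <- if (is.null(cfg$amputate)) list() else cfg$amputate
    rate <- if (is.null(acfg$target_rate)) 0.30 else acfg$target_rate
    slope <- if (is.null(acfg$slope)) 0.5 else acfg$slope
    psi0 <- calibrate_intercept(panel, slope, rate)
    mm <- missingness_model(psi0, slope, psi0, slope)
    panel <- apply_mar(panel, mm, seed = seeds[["amputate"]])
    paths$panel_mar <- file.path(cfg$out_dir, "panel_mar.csv")
    write_panel(panel, paths$panel_mar)
  }
  completed <- NULL
  if ("impute" %in% stages) {
    icfg <- if (is.null(cfg$impute)) list() else cfg$impute
    ic <- imputation_config(
      m = if (is.null(icfg$m)) 5 else icfg$m,
      sweeps = if (is.null(icfg$sweeps)) 10 else icfg$sweeps,
      method = if (is.null(icfg$method)) "multilevel" else icfg$method,
      seed = seeds[["impute"]])
    completed <- impute_panel(panel, ic)
    paths$imputed <- character(ic$m)
    for (k in seq_len(ic$m)) {
      paths$imputed[k] <- file.path(cfg$out_dir,
                                    sprintf("imputed_%02d.csv", k))
      write_panel(completed$panels[[k]], paths$imputed[k])
    }
  }
  if ("fit" %in% stages) {
    fcfg <- if (is.null(cfg$fit)) list() else cfg$fit
    st <- mcmc_settings_study(seed = seeds[["fit"]])
    for (f in c("chains", "iterations", "burn_in", "adaptation", "thin"))
      if (!is.null(fcfg[[f]])) st[[f]] <- as.integer(fcfg[[f]])
    variant <- if (is.null(fcfg$variant)) "complete" else fcfg$variant
    pd <- if (!is.null(completed)) {
      fits <- lapply(completed$panels, fit_mvar, spec = spec, settings = st)
      paths$summary <- file.path(cfg$out_dir, "summary.csv")
      utils::write.csv(pool_posterior(fits), paths$summary,
                       row.names = FALSE)
      fits[[1]]
    } else {
      fit1 <- switch(variant,
        complete = fit_mvar(panel, spec, settings = st),
        bfiml = fit_mvar_bfiml(panel, spec, settings = st),
        ld = fit_mvar(suppressWarnings(listwise_prepare(panel)), spec,
                      settings = st),
        stop("config schema violation: fit$variant must be complete|bfiml|ld"))
      paths$summary <- file.path(cfg$out_dir, "summary.csv")
      utils::write.csv(summarize_draws(fit1), paths$summary,
                       row.names = FALSE)
      fit1
    }
    paths$draws <- file.path(cfg$out_dir, "posterior.csv")
    write_draws(pd, paths$draws)
  }
  manifest <- file.path(cfg$out_dir, "run.manifest")
  writeLines(c(paste0("root_seed: ", cfg$seed),
               paste0("stages: ", paste(stages, collapse = ",")),
               paste0("stage_seeds: ",
                      paste(names(seeds), seeds, sep = "=",
                            collapse = ","))),
             manifest)
  paths$manifest <- manifest
  invisible(paths)
}
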