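#' Split-chain potential scale reduction factor
#'
#' Each chain is split in half and the classical ratio of pooled to
#' within-chain variance is computed over the split chains:
#' `R-hat = sqrt(((n-1)/n * W + B/n) / W)`. Chains that are all constant and
#' identical return 1 by convention.
#'
#' @param draws a `posterior_draws` object, or a list of numeric vectors /
#'   a matrix with one column per chain (draws in rows).
#' @return Named numeric of R-hat values (one per parameter for
#'   `posterior_draws` input; a scalar otherwise).
#' @export
rhat <- function(draws) {
  if (inherits(draws, "posterior_draws"))
    return(vapply(draws$params, function(pn)
      rhat(lapply(draws$draws, function(m) m[, pn])), 0))
  ch <- as_chain_list(draws)
  if (length(ch) < 2) stop("rhat needs at least 2 chains")
  half <- unlist(lapply(ch, function(v) {
    n2 <- floor(length(v) / 2)
    list(v[seq_len(n2)], v[n2 + seq_len(n2)])
  }), recursive = FALSE)
  n <- length(half[[1]])
  if (n < 5) stop("rhat needs at least 10 retained draws per chain")
  means <- vapply(half, mean, 0)
  vars <- vapply(half, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W < 1e-300) return(if (B < 1e-300) 1.0 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size
#'
#' Autocorrelation-based effective sample size combining chains: the lag
#' autocorrelations of the pooled process are estimated from the per-chain
#' autocovariances relative to the pooled variance, paired sums are truncated
#' at the first negative pair and made monotone (Geyer's initial monotone
#' sequence), and `ESS = M * n / (1 + 2 * sum(rho))`.
#'
#' @inheritParams rhat
#' @return Named numeric of ESS values (or a scalar).
#' @export
ess <- function(draws) {
  if (inherits(draws, "posterior_draws"))
    return(vapply(draws$params, function(pn)
      ess(lapply(draws$draws, function(m) m[, pn])), 0))
  ch <- as_chain_list(draws)
  M <- length(ch)
  n <- min(lengths(ch))
  ch <- lapply(ch, function(v) v[seq_len(n)])
  means <- vapply(ch, mean, 0)
  vars <- vapply(ch, stats::var, 0)
  W <- mean(vars)
  B <- if (M > 1) n * stats::var(means) else 0
  varplus <- (n - 1) / n * W + B / n
  if (varplus < 1e-300) return(M * n)
  maxlag <- min(n - 1, 2000)
  acov <- sapply(ch, function(v)
    stats::acf(v, lag.max = maxlag, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1])
  rho <- 1 - (W - rowMeans(acov)) / varplus  # rho[1] is lag 0
  # Geyer initial monotone positive sequence on paired sums
  npair <- floor((maxlag + 1) / 2)
  psum <- numeric(0)
  for (k in seq_len(npair)) {
    i <- 2 * (k - 1) + 1
    if (i + 1 > length(rho)) break
    s <- rho[i] + rho[i + 1]
    if (s < 0) break
    if (length(psum) && s > psum[length(psum)]) s <- psum[length(psum)]
    psum <- c(psum, s)
  }
  tau <- max(-1 + 2 * sum(psum), 1 / (M * n))
  min(M * n / tau, M * n * log10(M * n))
}

as_chain_list <- function(draws) {
  if (is.matrix(draws)) draws <- lapply(seq_len(ncol(draws)),
                                        function(j) draws[, j])
  if (!is.list(draws)) stop("expected a list of chains or a matrix")
  draws
}

#' Posterior summary with convergence diagnostics
#'
#' @param draws a `posterior_draws` object.
#' @return A data.frame with one row per parameter: posterior mean, sd,
#'   2.5%/97.5% quantiles (credible interval), split-chain R-hat and ESS,
#'   plus `flag` marking parameters with `R-hat >= 1.1` or `ESS < 300`.
#' @export
summarize_draws <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  all <- do.call(rbind, draws$draws)
  rh <- rhat(draws)
  es <- ess(draws)
  out <- data.frame(
    parameter = draws$params,
    mean = colMeans(all),
    sd = apply(all, 2, stats::sd),
    ci_low = apply(all, 2, stats::quantile, 0.025),
    ci_high = apply(all, 2, stats::quantile, 0.975),
    rhat = rh, ess = es,
    row.names = NULL)
  out$flag <- out$rhat >= 1.1 | out$ess < 300
  out
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("posterior_draws:", length(x$draws), "chains x",
      nrow(x$draws[[1]]), "retained draws,", length(x$params),
      "parameters\n")
  print(utils::head(summarize_draws(x), 12), digits = 3)
  invisible(x)
}
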