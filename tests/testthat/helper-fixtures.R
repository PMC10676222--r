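# shared fixtures: small panels and specs built in code

paper_spec <- function(...) mvar_spec(...)

# a tiny deterministic panel for structural tests
tiny_panel <- function(N = 3, Tn = 5, seed = 11) {
  set.seed(seed)
  rec <- data.frame(person_id = rep(seq_len(N), each = Tn),
                    t = rep(seq_len(Tn), N),
                    y1 = rnorm(N * Tn, 2), y2 = rnorm(N * Tn, 2),
                    x1 = rnorm(N * Tn), x2 = rnorm(N * Tn))
  panel_data(rec, data.frame(person_id = seq_len(N), x3 = rnorm(N)),
             meta = list(seed = seed))
}

# a quick simulated panel at the study's true values
sim_small <- function(N = 30, Tn = 30, icc = 0.5, seed = 5) {
  simulate_panel(sim_design(N = N, T_occasions = Tn, icc_target = icc,
                            seed = seed), paper_spec())
}

mar_panel <- function(panel, rate = 0.30, slope = 0.5, seed = 17) {
  psi0 <- calibrate_intercept(panel, slope, rate)
  apply_mar(panel, missingness_model(psi0, slope, psi0, slope), seed = seed)
}

fast_settings <- function(seed = 1, ...) {
  mcmc_settings_study(seed = seed, adaptation = 100, burn_in = 200,
                      iterations = 1000, ...)
}

# numerical-integration oracle for the degenerate model y_t ~ N(mu, s2),
# prior mu ~ N(0, 100), s2 ~ uniform(0, 100); the sampler's likelihood
# conditions on each person's first occasion, so the oracle sees y[-1]
grid_oracle <- function(y) {
  y <- y[-1]
  n <- length(y)
  s2g <- seq(0.2, 6, length.out = 1500)
  mug <- seq(min(y) - 3, max(y) + 3, length.out = 1500)
  ll <- matrix(0, length(mug), length(s2g))
  for (j in seq_along(s2g)) {
    v <- s2g[j]
    ll[, j] <- -n / 2 * log(v) -
      (sum(y^2) - 2 * mug * sum(y) + n * mug^2) / (2 * v) +
      dnorm(mug, 0, 10, log = TRUE)
  }
  w <- exp(ll - max(ll)); w <- w / sum(w)
  list(mu_mean = sum(rowSums(w) * mug),
       mu_sd = sqrt(sum(rowSums(w) * mug^2) - sum(rowSums(w) * mug)^2),
       s2_mean = sum(colSums(w) * s2g),
       s2_sd = sqrt(sum(colSums(w) * s2g^2) - sum(colSums(w) * s2g)^2))
}

# one synthetic EMA record with controllable item values
one_record <- function(urge = c(5, 5, 5), na = rep(1, 5), avail = 3,
                       pa = c(3, 3, 3), motiv = c(4, 4)) {
  df <- data.frame(person_id = 1,
                   timestamp = as.POSIXct("2006-03-01 14:00:00",
                                          tz = "UTC"),
                   ema_type = "random")
  df[paste0("urge", 1:3)] <- as.list(urge)
  df[paste0("na", 1:5)] <- as.list(na)
  df$avail <- avail
  df$lapse_count <- NA_integer_
  df$lapse_timeago <- NA_integer_
  df[paste0("pa", 1:3)] <- as.list(pa)
  df$selfeff <- 3
  df[paste0("motiv", 1:2)] <- as.list(motiv)
  df
}
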