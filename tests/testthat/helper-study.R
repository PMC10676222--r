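# The smoke-scale Monte Carlo study (20 replications at N = 50, T = 50,
# high ICC, all five missing-data methods) is shared by several acceptance
# checks; it is computed once per test run and cached.
.study_cache <- new.env(parent = emptyenv())

smoke_study <- function() {
  if (is.null(.study_cache$res)) {
    .study_cache$res <- run_study(
      conditions = data.frame(N = 50, T_occasions = 50, icc_target = 0.5),
      methods = c("complete", "slmi", "mlmi", "bfiml", "ld"),
      H = 20, seed = 1)[[1]]
  }
  .study_cache$res
}
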