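# Shared fixtures: small cohorts, plausible fraction sets, and a cached
# calibration against the published base-case endpoints (reused across
# test files to avoid refitting).

tiny_config <- function(n = 10000) sim_config(total_population = n)

plausible_fractions <- function() {
  flow_fractions(f_dev = 0.18, f_restore = 0.12, f_endo = 0.01,
                 f_loss = 0.15, f_rec_restore = 0.05, f_rec_endo = 0.05)
}

.fixture_cache <- new.env(parent = emptyenv())

published_fit <- function() {
  if (is.null(.fixture_cache$fit)) {
    .fixture_cache$fit <- calibrate_fractions(
      calibration_problem(base_case_targets()), seed = 1)
  }
  .fixture_cache$fit
}
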