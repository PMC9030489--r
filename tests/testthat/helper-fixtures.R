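# Shared synthetic fixtures, built once per test run and memoised.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# Default-effect study over all eight sensors at the default design size
# (30 subjects x 24 conditions x 2 repetitions), used for the
# factor-effect pattern checks.
fixture_effects_study <- function() {
  fixture("effects_study", function() {
    cfg <- study_config(n_subjects = 30, n_repetitions = 2, seed = 2026)
    simulate_study(cfg)
  })
}

fixture_effects_measures <- function() {
  fixture("effects_measures", function()
    compute_study_measures(fixture_effects_study()))
}

# Pelvis-only study for the classification checks (same study conditions,
# one placement to keep the waveform volume down).
fixture_class_study <- function() {
  fixture("class_study", function() {
    cfg <- study_config(n_subjects = 12, n_repetitions = 2,
                        sensor_set = "pelvis", seed = 11)
    simulate_study(cfg)
  })
}

# Small multi-sensor study for structural/unit tests.
fixture_small_study <- function() {
  fixture("small_study", function() {
    cfg <- study_config(n_subjects = 3, n_repetitions = 2,
                        sensor_set = c("pelvis", "T8"), seed = 7)
    simulate_study(cfg)
  })
}

# One directional-signals object of band-limited Gaussian sway.
gaussian_directions <- function(n = 2400, rate = 240, sd = 0.2, seed = 1) {
  set.seed(seed)
  acc <- matrix(rnorm(3 * n, 0, sd), n, 3)
  derive_directions(acc, rate, detrend_axes = TRUE)
}
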