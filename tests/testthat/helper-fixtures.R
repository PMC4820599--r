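# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# small geometry: 162-vertex folded surface, 60 sensors
tiny_geometry <- function() memo("tiny_geom", function() {
  cfg <- tiny_study_config()
  build_study_geometry(cfg)
})

tiny_study_config <- function(master_seed = 424242, ...) {
  study_config(n_location_pairs = 2, patch_areas = c(0, 2),
               couplings = 0.4, snr_levels = 0,
               subdivision_level = 2, n_sensors = 60,
               master_seed = master_seed, ...)
}

# the scaled-down replication study used by the acceptance checks
# (default study_config: 50 pairs x {0,2,4} cm^2 x {0.2,0.4} x {0,-20} dB)
acceptance_study <- function() memo("acceptance_study", function() {
  run_study(study_config(), verbose = FALSE)
})

# quick short-series oscillator for unit tests
short_spec <- function(...) {
  oscillator_spec(n_samples = 3000, ...)
}

rel_diff <- function(a, b) {
  max(abs(a - b)) / max(abs(b), .Machine$double.eps)
}
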