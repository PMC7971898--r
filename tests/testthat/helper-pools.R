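# Shared fixtures: pools are built (and calibrated) once per test run and
# cached, since calibration is the expensive step.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# raw (uncalibrated) default 200-unit pool
default_pool_raw <- function(seed = 1L) {
  cached(paste0("raw", seed), build_pool(muscle_config(), seed = seed))
}

# small calibrated pool for fast structural tests
small_pool <- function(n = 12L, seed = 3L) {
  cached(paste0("small", n, "_", seed), {
    calibrate_pool(build_pool(muscle_config(n_units = n), seed = seed))
  })
}

# the full calibrated default pool (used by the acceptance tests)
default_pool_calibrated <- function(seed = 1L) {
  cached(paste0("cal", seed), {
    calibrate_pool(build_pool(muscle_config(), seed = seed))
  })
}
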