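test_that("fusion is 0% for isolated twitches and 100% for a flat signal", {
  t <- seq(0, 3, by = 1e-3)
  # a 1 Hz twitch train whose last-second ripple equals the twitch amplitude
  tw <- function(tau) ifelse(tau > 0, (tau / 0.05) * exp(1 - tau / 0.05), 0)
  x <- tw(t %% 1)
  expect_equal(fusion_degree(x, t, max(x)), 0, tolerance = 0.5)
  expect_equal(fusion_degree(rep(2.2, length(t)), t, 1), 100)
  expect_error(fusion_degree(x, t, 0), "positive")
})

test_that("the periodogram resolves tones and preserves variance", {
  fs <- 1000
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- 3 * sin(2 * pi * 10 * t) + rnorm(length(t), sd = 0.1)
  psd <- welch_psd(x, fs)
  expect_equal(psd$freq[which.max(psd$power)], 10, tolerance = 0.06)
  expect_true(all(psd$power >= 0))
  # Parseval: integrated density within 5% of the signal variance
  set.seed(1)
  w <- rnorm(10 * fs)
  psdw <- welch_psd(w, fs, fmax = fs / 2)
  expect_equal(band_power(psdw, 0.5, fs / 2), var(w), tolerance = 0.05)
  # white noise is flat: halves of the band carry similar power
  lo <- band_power(psdw, 1, 250)
  hi <- band_power(psdw, 251, 500)
  expect_lt(abs(lo - hi) / (lo + hi), 0.1)
  expect_error(welch_psd(rnorm(100), fs), "short")
})

test_that("detrended segment statistics strip slow drift but keep noise", {
  fs <- 1000
  n <- 10 * fs
  set.seed(2)
  noise <- rnorm(n, sd = 0.5)
  drift <- seq(0, 8, length.out = n)
  st <- munoise:::segment_stats(100 + drift + noise, fs)
  # raw SD is dominated by the drift; detrended recipes recover the noise
  expect_gt(st$sd_raw, 2)
  expect_equal(st$sd_detrend1, 0.5, tolerance = 0.05)
  expect_equal(st$sd_detrend2, 0.5, tolerance = 0.05)
  expect_equal(st$cov_detrend1, 100 * st$sd_detrend1 / st$mean)
})

test_that("pair sampling agrees with exhaustive enumeration", {
  pool <- build_pool(muscle_config(n_units = 30L), seed = 4L)
  # hand-set peak rates: reverse-onion for a known fraction of pairs
  pool$units$PDR <- 20 + pool$units$RT * 10 + c(rep(0, 15), rep(-5, 15))
  pool$calibrated <- TRUE
  ex <- onion_skin_pair_analysis(pool, exhaustive = TRUE)
  sam <- onion_skin_pair_analysis(pool, n_pairs = 300, seed = 6)
  expect_equal(sam$fraction_reverse, ex$fraction_reverse, tolerance = 0.12)
  expect_identical(ex$n_pairs, 435L)
  # constant PDR: ties count as inconsistent on both sides -> fraction 0
  pool$units$PDR <- rep(30, 30)
  expect_equal(onion_skin_pair_analysis(pool, exhaustive = TRUE)$fraction_reverse, 0)
})

test_that("correlation reports recover a constructed rank relationship", {
  pool <- build_pool(muscle_config(n_units = 50L), seed = 5L)
  pool$units$f0_5 <- 5 + 0.1 * seq_len(50)     # rate rank = size rank
  pool$units$MDR <- 0.5 * pool$units$f0_5
  pool$units$PDR <- 2 * pool$units$f0_5
  pool$calibrated <- TRUE
  rep <- correlation_reports(pool, ueff = 0.2)
  expect_gt(rep$r_pdr_rt, 0.8)     # speed-matched pool (RT is exponential)
  expect_lt(rep$r_dr_rt, 0)        # onion-skin pattern at submaximal drive
  expect_error(correlation_reports(pool, ueff = 0.005), "active")
})

test_that("configurations validate, default, and round-trip", {
  cfg <- load_config()
  expect_equal(cfg$n_units, 200L)
  expect_equal(cfg$rp, 25)
  expect_equal(cfg$ur, 0.8)
  path <- tempfile(fileext = ".yaml")
  writeLines("", path)            # empty file -> full defaults
  expect_equal(load_config(path), cfg)
  write_config(cfg, path)
  expect_equal(load_config(path), cfg)
  writeLines("ur: 1.2", path)
  expect_error(load_config(path), "u1 < ur")
  writeLines("not_a_key: 3", path)
  expect_error(load_config(path), "unknown config key")
})

test_that("the sensitivity suite and pipeline driver run end to end", {
  # reduced problem size: a 12-unit pool, one level, one short trial
  m <- muscle_config(n_units = 12L)
  proto <- trial_protocol(hold_s = 5, analysis_s = 4, n_trials = 1)
  suite <- sensitivity_suite(m, levels = 0.5, protocol = proto, seed = 3,
                             scenarios = c("base", "no_see", "onion_skin"))
  expect_named(suite, c("base", "no_see", "onion_skin"))
  # removing the series-elastic element raises both output and variability
  expect_gt(suite$no_see$fmax, suite$base$fmax)
  expect_gt(suite$no_see$summary$sd_detrend2, suite$base$summary$sd_detrend2)
  # the onion-skin scheme caps large units at 25-35 Hz, cutting maximal force
  expect_lt(suite$onion_skin$fmax, suite$base$fmax)

  out <- tempfile("runall")
  cfg <- load_config()
  cfg$n_units <- 10L
  cfg$levels <- 0.4
  cfg$n_trials <- 1
  man <- run_all(cfg, seed = 5, out_dir = out)
  expect_true(file.exists(file.path(out, "pool.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  s1 <- read.csv(file.path(out, "population_summary.csv"))
  # idempotent: a second call reuses cached stages and leaves outputs intact
  man2 <- run_all(cfg, seed = 5, out_dir = out)
  expect_equal(man2$stages$pool, "cached")
  s2 <- read.csv(file.path(out, "population_summary.csv"))
  expect_identical(s1, s2)
  pool_back <- read_pool_csv(file.path(out, "pool.csv"))
  expect_identical(nrow(pool_back$units), 10L)
  expect_true(pool_back$calibrated)
})
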