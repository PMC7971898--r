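# Rate coding uses only RT/MDR/PDR/f0.5, so these tests run on a pool with
# hand-set discharge limits instead of a calibrated one.

fake_pool <- function(n = 40, u1 = 0.01, ur = 0.8) {
  pool <- build_pool(muscle_config(n_units = n, u1 = u1, ur = ur), seed = 2L)
  f05 <- 1000 / (1.18 * pool$units$CT_ms)  # speed-matched rates
  pool$units$f0_5 <- f05
  pool$units$MDR <- 0.5 * f05
  pool$units$PDR <- 2 * f05
  pool$units$plateau <- 0.95
  pool$calibrated <- TRUE
  pool
}

test_that("discharge rates anchor at MDR on recruitment and PDR at full drive", {
  pool <- fake_pool()
  u <- pool$units
  at_rt <- vapply(seq_len(nrow(u)), function(i)
    discharge_rate(pool, u$RT[i])[i], numeric(1))
  expect_equal(at_rt, u$MDR, tolerance = 1e-9)
  expect_equal(discharge_rate(pool, 1), u$PDR, tolerance = 1e-9)
  expect_equal(unname(discharge_rate(pool, 0)), rep(0, nrow(u)))
  expect_error(discharge_rate(pool, 1.2), "0, 1")
})

test_that("the low-threshold bilinear branch is continuous and saturating", {
  pool <- fake_pool()
  tab <- munoise:::rate_coding_table(pool$units)
  bil <- which(tab[, "scheme"] == 1)
  expect_gt(length(bil), 5)
  expect_true(all(tab[bil, "RT"] <= 0.1))
  for (i in bil[c(1, length(bil) %/% 2, length(bil))]) {
    Ut <- tab[i, "Ut"]
    left <- discharge_rate(pool, Ut - 1e-9)[i]
    right <- discharge_rate(pool, Ut + 1e-9)[i]
    expect_equal(left, right, tolerance = 1e-5)
    # transition happens at f_t * f0.5
    expect_equal(left, unname(1.1 * tab[i, "f05"]), tolerance = 1e-3)
    # steep region slope exceeds the saturated region slope
    expect_gt(tab[i, "lamke"], tab[i, "ke"])
  }
})

test_that("discharge rate is non-decreasing in synaptic input for all units", {
  pool <- fake_pool()
  grid <- seq(0, 1, by = 0.01)
  rates <- vapply(grid, function(u) discharge_rate(pool, u),
                  numeric(nrow(pool$units)))
  for (i in seq_len(nrow(pool$units)))
    expect_true(all(diff(rates[i, ]) > -1e-9), label = paste("unit", i))
})

test_that("onion-skin scheme fixes 8 Hz onset and 35..25 Hz peak rates", {
  pool <- apply_onion_skin(fake_pool())
  u <- pool$units
  expect_equal(unname(u$MDR), rep(8, nrow(u)))
  expect_equal(u$PDR[1], 35)
  expect_equal(u$PDR[nrow(u)], 25)
  dr1 <- discharge_rate(pool, 1)
  expect_equal(dr1[1], 35)
  expect_equal(dr1[nrow(u)], 25)
  at_rt <- vapply(seq_len(nrow(u)), function(i)
    discharge_rate(pool, u$RT[i])[i], numeric(1))
  expect_equal(at_rt, rep(8, nrow(u)))
})

test_that("the input-dependent ISI variability law decays from 30% to 10%", {
  p <- rate_coding_params(cv_mode = "input_dependent")
  expect_equal(munoise:::isi_cv(0.2, 0.2, p), 30)
  expect_lt(munoise:::isi_cv(0.5, 0.2, p), 10.01)
  cvs <- munoise:::isi_cv(seq(0.2, 0.6, 0.05), 0.2, p)
  expect_true(all(diff(cvs) < 0))
})

test_that("spike trains are periodic without noise and match the CoV with it", {
  pool <- fake_pool()
  unit <- pool$units[10, ]
  const_u <- function(t) 0.5
  p0 <- rate_coding_params(cv_mode = "constant", cv_constant = 0)
  spk <- generate_spike_train(unit, const_u, 3, p0)
  dr <- discharge_rate(pool, 0.5)[10]
  expect_equal(unname(diff(spk)), rep(1 / dr, length(spk) - 1),
               tolerance = 1e-9)
  expect_equal(spk[1], 0)  # recruited at t = 0, first spike at crossing

  # sample CoV of ISIs ~ 20%; truncation at 3.9 SD shrinks it by < 0.1%
  p20 <- rate_coding_params(cv_mode = "constant", cv_constant = 20)
  set.seed(42)
  isis <- unlist(lapply(1:40, function(j)
    diff(generate_spike_train(unit, const_u, 3, p20))))
  expect_gt(length(isis), 1000)
  expect_equal(100 * sd(isis) / mean(isis), 20 * 0.99922, tolerance = 0.1)

  # identical seeds give identical trains
  set.seed(11)
  s1 <- generate_spike_train(unit, const_u, 3, p20)
  set.seed(11)
  s2 <- generate_spike_train(unit, const_u, 3, p20)
  expect_identical(s1, s2)

  # silent below threshold; no spikes before the ramp crosses RT
  ramp <- function(t) t / 4
  spk2 <- generate_spike_train(unit, ramp, 3, p0)
  expect_gte(spk2[1], 4 * unit$RT - 1e-3)
})

test_that("mean discharge rate of active units rises with force level", {
  pool <- fake_pool()
  fake_curve <- data.frame(ueff = seq(0.05, 1, 0.05),
                           force_pct = seq(5, 100, 5))  # monotone stand-in
  prof <- mean_rate_profile(pool, c(11, 21, 50, 72, 93), fake_curve)
  expect_true(all(diff(prof$mean_dr) > 0))
  expect_true(all(diff(prof$n_active) >= 0))
  # onion-skin: rate modulation is compressed (8 Hz onset, 25-35 Hz cap), so
  # the profile rises far less and tops out below the speed-matched scheme
  prof_os <- mean_rate_profile(apply_onion_skin(pool),
                               c(11, 21, 50, 72, 93), fake_curve)
  expect_lt(max(prof_os$mean_dr), max(prof$mean_dr))
  expect_lt(diff(range(prof_os$mean_dr)), diff(range(prof$mean_dr)))
  expect_error(mean_rate_profile(pool, 150, fake_curve), "outside")
})
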