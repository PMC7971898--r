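test_that("the twitch-summation pool spans the prescribed parameter ranges", {
  fp <- fuglevand_pool()
  expect_equal(nrow(fp), 120)
  expect_equal(fp$P[120] / fp$P[1], 100^(119 / 120), tolerance = 1e-9)
  expect_equal(max(fp$T_ms) / min(fp$T_ms), 3^(119 / 120), tolerance = 1e-2)
  expect_equal(fp$RTE[120] / fp$RTE[1], 68^(119 / 120), tolerance = 1e-9)
  # recruitment complete at 80% of maximal excitation
  expect_equal(fp$RTE[120] / attr(fp, "Emax"), 0.8)
  expect_equal(range(fp$PFR), c(25, 35 - 10 * fp$RTE[1] / fp$RTE[120]),
               tolerance = 1e-6)
})

test_that("a single twitch peaks at P after one contraction time with gain 1", {
  f <- fuglevand_unit_force(0.05, P = 2.5, T_ms = 60, duration = 0.6,
                            dt = 1e-4)
  t <- seq(0, by = 1e-4, length.out = length(f))
  expect_equal(max(f), 2.5, tolerance = 1e-3)           # gain 1, peak P
  expect_equal(t[which.max(f)] - 0.05, 0.060, tolerance = 2e-4)
})

test_that("the filter update matches a brute-force convolution", {
  spikes <- c(0.05, 0.07, 0.11, 0.13, 0.18, 0.30)
  P <- 1.7; T_ms <- 45
  dt <- 1e-4
  f <- fuglevand_unit_force(spikes, P, T_ms, duration = 0.8, dt = dt)
  t <- seq(0, by = dt, length.out = length(f))
  # independent oracle: explicit per-spike superposition of Eq-1 twitches
  gains <- munoise:::fuglevand_gain((T_ms / 1000) / c(Inf, diff(spikes)))
  oracle <- rowSums(vapply(seq_along(spikes), function(j) {
    tau <- pmax(t - spikes[j], 0)
    gains[j] * P * (tau / (T_ms / 1000)) * exp(1 - tau / (T_ms / 1000))
  }, numeric(length(t))))
  # the filter adds impulses on the step grid; compare away from spike steps
  expect_lt(max(abs(f - oracle)) / max(oracle), 5e-3)
})

test_that("long 100 Hz train plateau matches the convolution oracle", {
  spikes <- seq(0, 2.99, by = 0.01)
  f <- fuglevand_unit_force(spikes, P = 1, T_ms = 90, duration = 3, dt = 1e-3)
  t <- seq(0, by = 1e-3, length.out = length(f))
  gains <- munoise:::fuglevand_gain(0.09 / c(Inf, diff(spikes)))
  sel <- t >= 2.5
  oracle <- vapply(t[sel], function(tt) {
    tau <- tt - spikes[spikes <= tt]
    sum(gains[spikes <= tt] * (tau / 0.09) * exp(1 - tau / 0.09))
  }, numeric(1))
  expect_equal(mean(f[sel]), mean(oracle), tolerance = 1e-3)
})

test_that("the twitch-summation model keeps its documented fusion defects", {
  # fusion vs rate over the pool: existence of non-monotonic units and of
  # fast units that never approach complete fusion
  fp <- fuglevand_pool()
  rates <- c(5, 8, 12, 16, 20, 25, 30, 35, 40, 50, 60)
  fus <- function(i, r) {
    spikes <- seq(0, 3 - 1e-9, by = 1 / r)
    f <- fuglevand_unit_force(spikes, fp$P[i], fp$T_ms[i], 3, dt = 1e-3)
    tw <- fuglevand_unit_force(0, fp$P[i], fp$T_ms[i], 1, dt = 1e-3)
    fusion_degree(f, seq(0, by = 1e-3, length.out = length(f)), max(tw))
  }
  curves <- vapply(c(1, 40, 80, 110, 120), function(i)
    vapply(rates, function(r) fus(i, r), numeric(1)), numeric(length(rates)))
  nonmono <- apply(curves, 2, function(cv) any(diff(cv) < -1))
  expect_true(any(nonmono))
  # the fastest units stay far from 100% fusion at their peak rates (25 Hz)
  f120 <- fus(120, 25)
  expect_lt(f120, 85)
})

test_that("the noise filter is linear in its input with slope set by sigma_c", {
  # sigma_c = 0: deterministic, SD identically zero
  s0 <- todorov_sd_slope(u_levels = c(0.2, 0.6, 1), n_trials = 2,
                         sigma_c = 0, duration = 12, seed = 5)
  expect_equal(s0$slope, 0, tolerance = 1e-12)
  expect_equal(s0$table$sd, rep(0, 3), tolerance = 1e-12)
  # multiplicative noise through a linear filter: SD proportional to u
  s <- todorov_sd_slope(u_levels = seq(0.2, 1, 0.2), n_trials = 6,
                        duration = 12, seed = 5)
  expect_gt(s$slope, 0)
  expect_lt(abs(s$intercept), 0.15 * s$slope)
  rel <- s$table$sd / s$table$u
  expect_lt(diff(range(rel)) / mean(rel), 0.25)
})

test_that("the empirical SD-mean power law is anchored at 2.34% at 100% MVC", {
  expect_equal(jones_sd_curve(100), 2.34)
  expect_equal(jones_sd_curve(50) / jones_sd_curve(25), 2^1.05,
               tolerance = 1e-12)
  expect_lt(jones_sd_curve(1e-6), 1e-6)
  expect_error(jones_sd_curve(150), "levels")
})
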