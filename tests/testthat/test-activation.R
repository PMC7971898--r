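slow_par <- munoise:::seed_params("slow")
fast_par <- munoise:::seed_params("fast")

test_that("the calcium cascade is quiescent without spikes and unimodal after one", {
  tr0 <- simulate_activation(numeric(0), slow_par, duration = 0.5)
  expect_equal(max(abs(tr0$A)), 0)
  expect_equal(max(abs(tr0$cf)), 0)

  tw <- simulate_activation(0, slow_par, duration = 5, sag_mode = "hold")
  i_pk <- which.max(tw$A)
  expect_gt(tw$A[i_pk], 0)
  expect_gt(i_pk, 1)
  # rises then falls: monotone up to the peak, decaying after
  expect_true(all(diff(tw$A[1:i_pk]) >= -1e-12))
  expect_lt(tw$A[length(tw$A)], 1e-3 * tw$A[i_pk])
  # bound state stays a fraction
  expect_true(all(tw$cf >= 0 & tw$cf <= 1))
})

test_that("refining the integration step leaves trajectories unchanged", {
  spikes <- periodic_train(12, 1.5)
  for (par in list(slow_par, fast_par)) {
    a1 <- simulate_activation(spikes, par, 1.5, dt = 1e-4)$A
    a2 <- simulate_activation(spikes, par, 1.5, dt = 1e-5)$A
    a2d <- a2[seq(1, length(a2), by = 10)]
    rms <- sqrt(mean((a1 - a2d)^2)) / max(a2d)
    expect_lt(rms, 1e-3)
  }
})

test_that("the Hill stage has its half-point at K and saturates", {
  expect_equal(hill_stage(0.3, N_hill = 4, K_hill = 0.3), 0.5)
  expect_equal(hill_stage(0, N_hill = 4, K_hill = 0.3), 0)
  expect_gt(hill_stage(50, N_hill = 4, K_hill = 0.3), 0.999)
  x <- seq(0, 2, by = 0.01)
  y <- hill_stage(x, N_hill = 3, K_hill = 0.4)
  expect_true(all(diff(y) > 0))
  # sag and yield scale the operating point multiplicatively
  expect_equal(hill_stage(0.2, S = 2, Y = 1, N_hill = 3, K_hill = 0.4),
               hill_stage(0.4, N_hill = 3, K_hill = 0.4))
})

test_that("length scaling is the identity at L0 and matches the affine form", {
  p <- slow_par
  expect_identical(length_scale_params(p, 1), p)
  p2 <- p
  p2[c("phi_short", "phi_long")] <- 0
  expect_identical(length_scale_params(p2, 0.8), p2)
  p3 <- p
  p3["phi_short"] <- 1
  p3["k3"] <- 2
  # hand evaluation: x = 1 * 2 * (1 - 0.8) + 2 = 2.4
  expect_equal(length_scale_params(p3, 0.8)[["k3"]], 2.4)
  w <- capture_warnings(length_scale_params(`[<-`(p3, "phi_short", -60), 0.9))
  expect_true(any(grepl("clamped", w)))
})

test_that("mean activation rises monotonically with stimulus rate", {
  for (par in list(slow_par, fast_par)) {
    ct <- twitch_response(par)$ct_ms / 1000
    rates <- (1 / ct) * c(0.25, 0.5, 0.75, 1, 1.5, 2, 3)
    ma <- vapply(rates, function(r)
      munoise:::mean_activation_at(par, r, dt = 2e-4), numeric(1))
    expect_true(all(diff(ma) > 0))
  }
})

test_that("the first-order output stage behaves like its analytic solution", {
  # activation filter: constant drive reaches (1 - exp(-t/tau3)) of the target
  p <- slow_par
  plat <- plateau_activation(p, dt = 2e-4)
  tr <- simulate_activation(periodic_train(plat$rate, 3), p, 3, dt = 2e-4)
  a_ss <- mean(tr$A[tr$time >= 2])
  # fully fused response: ripple well under the twitch scale
  expect_lt(diff(range(tr$A[tr$time >= 2])), 0.02 * a_ss)
  expect_equal(a_ss, plat$plateau, tolerance = 0.01)
})

test_that("calibration recovers contraction-time and twitch-tetanus targets", {
  set.seed(31)
  for (tg in list(c(50, 0.23), c(70, 0.4), c(30, 0.12))) {
    cal <- calibrate_unit(tg[1], tg[2], "slow")
    expect_equal(cal$ct_ms, tg[1], tolerance = 0.05)
    expect_equal(cal$tt, tg[2], tolerance = 0.10)
    # re-simulate independently from the returned parameters
    tw <- twitch_response(cal$par, duration = 1.2)
    expect_equal(tw$ct_ms, tg[1], tolerance = 0.05)
  }
  set.seed(32)
  calf <- calibrate_unit(25, 0.3, "fast")
  expect_equal(calf$ct_ms, 25, tolerance = 0.05)
  expect_equal(calf$tt, 0.3, tolerance = 0.10)
})

test_that("f0.5 sits at half the plateau by construction", {
  set.seed(33)
  cal <- calibrate_unit(45, 0.25, "slow")
  fr <- find_f0_5(cal$par)
  ma <- munoise:::mean_activation_at(cal$par, fr$f0_5)
  expect_equal(ma, 0.5 * fr$plateau, tolerance = 5e-3)
})

test_that("calibrated pools are reproducible and speed-matched", {
  pool <- small_pool()
  u <- pool$units
  expect_true(all(is.finite(u$f0_5)))
  expect_identical(u$MDR, 0.5 * u$f0_5)
  expect_identical(u$PDR, 2 * u$f0_5)
  # tau2/tau3 scale with contraction time: slow units above fast units
  expect_gt(min(u$tau2[u$fiber_type == "slow"]),
            max(u$tau2[u$fiber_type == "fast"]))
  expect_gt(min(u$tau3[u$fiber_type == "slow"]),
            max(u$tau3[u$fiber_type == "fast"]))
  # gamma and the Hill exponent are common to all units
  expect_equal(length(unique(u$gamma)), 1L)
  expect_equal(length(unique(u$N_hill)), 1L)
  # same seed, same pool
  pool2 <- calibrate_pool(build_pool(muscle_config(n_units = 12L), seed = 3L))
  expect_identical(pool$units, pool2$units)
})

test_that("phi fitting recovers a known length-dependence coefficient", {
  set.seed(34)
  cal <- calibrate_unit(40, 0.25, "slow")
  truth <- cal$par
  truth["phi_short"] <- 0.8
  truth["phi_long"] <- 0.5
  f05 <- find_f0_5(cal$par, dt = 2e-4)$f0_5
  grid <- expand.grid(Lce = c(0.8, 0.9, 1.1, 1.2),
                      rate_hz = f05 * c(0.6, 1, 1.6))
  grid$mean_activation <- vapply(seq_len(nrow(grid)), function(j)
    munoise:::mean_activation_at(truth, grid$rate_hz[j], dt = 2e-4,
                                 Lce = grid$Lce[j]), numeric(1))
  fit <- fit_phi(cal$par, grid, dt = 2e-4)
  expect_equal(fit[["phi_short"]], 0.8, tolerance = 0.05)
  expect_equal(fit[["phi_long"]], 0.5, tolerance = 0.05)
  expect_warning(fit0 <- fit_phi(cal$par, NULL), "phi set to 0")
  expect_equal(fit0[["phi_short"]], 0)
})
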