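test_that("maximal tetanic force follows the architectural formula", {
  # hand evaluation of M*cos(alpha)*eps/(rho*L) with the default constants
  expect_equal(compute_F0(muscle_config()), 652.497377, tolerance = 1e-8)
  # pennation 0 removes the cosine projection
  m0 <- muscle_config(pennation = 1e-12)
  expect_equal(compute_F0(m0), 150 * 31.8 / (1.06 * 6.8), tolerance = 1e-9)
  # linear in muscle mass
  m2 <- muscle_config(muscle_mass = 300)
  expect_equal(compute_F0(m2), 2 * compute_F0(muscle_config()))
  expect_error(muscle_config(muscle_mass = -1), "positive")
})

test_that("tetanic forces are exponential, normalized, and right-skewed", {
  # two-unit hand case: b = ln(4)/2 so exp(b) = 2 and PT = (1/3, 2/3)
  expect_equal(assign_tetanic_forces(2, 4, 1), c(1, 2) / 3, tolerance = 1e-12)
  for (cfg in list(c(200, 25), c(50, 100), c(10, 3))) {
    PT <- assign_tetanic_forces(cfg[1], cfg[2], 652.5)
    expect_equal(sum(PT), 652.5, tolerance = 1e-9)
    expect_true(all(diff(PT) > 0))
    # discrete indexing: PT_N / PT_1 = RP^((N-1)/N)
    expect_equal(PT[cfg[1]] / PT[1], cfg[2]^((cfg[1] - 1) / cfg[1]),
                 tolerance = 1e-9)
    expect_lt(median(PT), mean(PT))
  }
})

test_that("fiber-type split puts 147 of 200 default units in the slow class", {
  pool <- default_pool_raw()
  expect_identical(pool$n_slow, 147L)
  expect_identical(sum(pool$units$fiber_type == "slow"), 147L)
  # brute-force 4-unit case: cumulative shares 0.052/0.167/0.424/1, so the
  # third unit crosses the 40% threshold
  PT4 <- assign_tetanic_forces(4, 25, 1)
  expect_identical(assign_fiber_types(PT4, 0.4)$n_slow, 3L)
  # fraction -> 1 labels every unit slow
  expect_identical(assign_fiber_types(PT4, 0.999999)$n_slow, 4L)
  # no PT overlap between types
  u <- pool$units
  expect_lt(max(u$PT[u$fiber_type == "slow"]),
            min(u$PT[u$fiber_type == "fast"]))
})

test_that("contraction times span the range with no cross-type overlap", {
  pool <- default_pool_raw()
  u <- pool$units
  expect_true(all(u$CT_ms >= 20 & u$CT_ms <= 85))
  expect_equal(range(u$CT_ms), c(20, 85), tolerance = 1e-9)
  slow_ct <- u$CT_ms[u$fiber_type == "slow"]
  fast_ct <- u$CT_ms[u$fiber_type == "fast"]
  expect_gt(min(slow_ct), max(fast_ct))
  # within type, contraction time is shuffled against size
  expect_lt(abs(cor(u$PT[u$fiber_type == "slow"], slow_ct)), 0.2)
  expect_lt(abs(cor(u$PT[u$fiber_type == "fast"], fast_ct)), 0.35)
})

test_that("twitch-tetanus ratios hit mean, range and correlation targets", {
  pool <- default_pool_raw()
  u <- pool$units
  expect_true(all(u$tt_ratio >= 0.07 & u$tt_ratio <= 0.53))
  expect_equal(mean(u$tt_ratio), 0.23, tolerance = 0.02)
  slow <- u$fiber_type == "slow"
  expect_equal(cor(u$tt_ratio[slow], u$CT_ms[slow]), 0.638, tolerance = 0.05)
  expect_equal(cor(u$tt_ratio[!slow], u$CT_ms[!slow]), 0.704,
               tolerance = 0.05)
  # zero jitter (corr target 1) gives a perfect rank map
  tt1 <- assign_twitch_tetanus_ratios(u$CT_ms, u$fiber_type, corr_slow = 1,
                                      corr_fast = 1, seed = 9)
  expect_equal(cor(tt1[slow], u$CT_ms[slow]), 1, tolerance = 1e-3)
  expect_error(assign_twitch_tetanus_ratios(u$CT_ms, u$fiber_type,
                                            corr_slow = 1.2),
               "correlation")
})

test_that("recruitment thresholds are exponential with exact endpoints", {
  RT <- assign_recruitment_thresholds(200, 0.01, 0.8)
  expect_equal(RT[1], 0.01)
  expect_equal(RT[200], 0.8, tolerance = 1e-12)
  expect_true(all(diff(RT) > 0))
  expect_equal(assign_recruitment_thresholds(2, 0.01, 0.8), c(0.01, 0.8))
  # size principle: threshold rank equals size rank exactly
  pool <- default_pool_raw()
  expect_equal(cor(pool$units$RT, pool$units$PT, method = "spearman"), 1)
})

test_that("pool construction is reproducible and serializes to CSV", {
  p1 <- build_pool(muscle_config(), seed = 7L)
  p2 <- build_pool(muscle_config(), seed = 7L)
  expect_identical(p1$units, p2$units)
  p3 <- build_pool(muscle_config(), seed = 8L)
  expect_false(identical(p1$units$CT_ms, p3$units$CT_ms))

  path <- tempfile(fileext = ".csv")
  write_pool_csv(p1, path)
  back <- read_pool_csv(path)
  expect_equal(back$units$PT, p1$units$PT, tolerance = 1e-8)
  expect_identical(back$units$fiber_type, p1$units$fiber_type)
  expect_equal(back$muscle$rp, p1$muscle$rp)
})
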