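# Activation dynamics: spike trains -> motor unit activation through the
# three-stage cascade (calcium kinetics, Hill nonlinearity with sag/yield,
# first-order filter), plus per-unit calibration against contraction-time and
# twitch-tetanus targets and the empirical determination of f0.5.

#' Simulate the activation of one isolated unit
#'
#' Integrates the calcium-kinetics / Hill / first-order cascade (fixed-step
#' RK4) for a given spike train at a fixed normalized fascicle length and zero
#' velocity (isolated unit, no series-elastic element).
#'
#' @param spike_times sorted spike times (s)
#' @param par named activation-parameter vector (see [seed_params()])
#' @param duration simulated duration (s)
#' @param dt integration step for the unit states (s); 1e-4 for single-unit work
#' @param Lce normalized fascicle length (1 = optimal)
#' @param sag_mode `"hold"` keeps the sag state at its sustained-discharge
#'   value (used for twitch references), `"dynamic"` integrates the sag state
#'   from its resting value, `"low_rate"` keeps the low-rate sag target
#'   engaged (discharge below 0.1 * f0.5)
#' @return list with `time`, `A` (activation) and `cf` (bound myofilament
#'   fraction) sampled every `dt`
#' @export
simulate_activation <- function(spike_times, par, duration, dt = 1e-4,
                                Lce = 1,
                                sag_mode = c("dynamic", "hold", "low_rate")) {
  sag_mode <- match.arg(sag_mode)
  sy <- sag_yield_constants()
  mode <- c(dynamic = 1L, hold = 0L, low_rate = 2L)[[sag_mode]]
  out <- simulate_unit_cpp(as.numeric(spike_times), par[act_par_names], dt,
                           duration, Lce, mode, sy$aS1, sy$aS2, sy$TS, sy$cY,
                           sy$VY, sy$TY)
  list(time = seq(0, by = dt, length.out = length(out$A)), A = out$A,
       cf = out$cf)
}

# Periodic spike train at `rate` Hz starting at t = 0.
periodic_train <- function(rate, duration) {
  if (rate <= 0) return(numeric(0))
  seq(0, duration - 1e-9, by = 1 / rate)
}

#' Single-twitch response and its summary measures
#'
#' Response to one spike with the sag state held at its sustained-discharge
#' value (the non-potentiated twitch used as the reference for contraction
#' time, twitch-tetanus ratio and the fusion denominator).
#'
#' @inheritParams simulate_activation
#' @return list with `peak` (peak activation), `ct_ms` (time to peak, ms),
#'   `trace` (the full simulation)
#' @export
twitch_response <- function(par, duration = 1, dt = 1e-4, Lce = 1) {
  tr <- simulate_activation(0, par, duration, dt, Lce, sag_mode = "hold")
  i <- which.max(tr$A)
  list(peak = tr$A[i], ct_ms = tr$time[i] * 1000, trace = tr)
}

# Mean activation over the last 1 s of a 3-s periodic train.
mean_activation_at <- function(par, rate, dt = 1e-4, Lce = 1, duration = 3) {
  tr <- simulate_activation(periodic_train(rate, duration), par, duration, dt,
                            Lce)
  mean(tr$A[tr$time >= duration - 1])
}

#' Plateau (maximal) activation of a unit
#'
#' Operationalized as the mean activation (last 1 s of a 3-s train) at the
#' lowest stimulus rate for which a further 20% rate increase changes the mean
#' activation by less than 0.5%.
#'
#' @inheritParams simulate_activation
#' @param r0 starting rate for the scan (Hz); defaults to the inverse twitch
#'   contraction time
#' @return list with `plateau` and the saturating `rate` (Hz)
#' @export
plateau_activation <- function(par, dt = 1e-4, Lce = 1, r0 = NULL) {
  if (is.null(r0)) {
    ct <- twitch_response(par, dt = dt, Lce = Lce)$ct_ms / 1000
    r0 <- 1 / ct
  }
  r <- r0
  a <- mean_activation_at(par, r, dt, Lce)
  for (k in 1:25) {
    a2 <- mean_activation_at(par, 1.2 * r, dt, Lce)
    if (abs(a2 - a) < 0.005 * a2) {
      return(list(plateau = a2, rate = 1.2 * r))
    }
    r <- 1.2 * r
    a <- a2
  }
  stop("activation-frequency curve did not plateau below ", round(r),
       " Hz; last mean activation ", signif(a, 4))
}

#' Empirical half-maximum discharge rate f0.5
#'
#' Root-finds the stimulus rate at which the mean activation (last 1 s of a
#' 3-s periodic train) equals 50% of the unit's plateau activation. The mean
#' activation is monotone in rate for calibrated units, so the root is unique.
#'
#' @inheritParams simulate_activation
#' @param plateau optionally a precomputed [plateau_activation()] result
#' @return list with `f0_5` (Hz), `plateau`, `plateau_rate`
#' @export
find_f0_5 <- function(par, dt = 1e-4, Lce = 1, plateau = NULL) {
  if (is.null(plateau)) plateau <- plateau_activation(par, dt, Lce)
  target <- 0.5 * plateau$plateau
  g <- function(r) mean_activation_at(par, r, dt, Lce) - target
  lo <- plateau$rate / 64
  hi <- plateau$rate
  glo <- g(lo)
  while (glo > 0 && lo > 0.05) {
    lo <- lo / 2
    glo <- g(lo)
  }
  if (glo > 0) stop("could not bracket f0.5 from below (rate ", lo, " Hz)")
  root <- uniroot(g, c(lo, hi), f.lower = glo, tol = 1e-3)
  list(f0_5 = root$root, plateau = plateau$plateau,
       plateau_rate = plateau$rate)
}

# Twitch-tetanus ratio of a parameter set: single-twitch peak over plateau.
measure_tt <- function(par, dt = 1e-4, plateau = NULL) {
  tw <- twitch_response(par, dt = dt)
  if (is.null(plateau)) plateau <- plateau_activation(par, dt = dt)$plateau
  tw$peak / plateau
}

# Uniform time dilation: rate constants scaled by s, time constants by 1/s.
# The trajectory maps exactly onto itself in rescaled time, so the twitch
# shape (and the twitch-tetanus ratio) is invariant while CT scales by 1/s.
rescale_time <- function(par, s) {
  rates <- c("k1", "k2", "k3", "k4i")
  taus <- c("tau1", "tau2", "tau3")
  par[rates] <- par[rates] * s
  par[taus] <- par[taus] / s
  par
}

#' Calibrate one unit's activation parameters
#'
#' Starting from the fiber-type seed set, applies a seeded log-normal
#' perturbation to a subset of parameters, bisection on `k1` to reach the
#' twitch-tetanus target, and a final exact time rescaling of all rate/time
#' constants to reach the contraction-time target (time dilation leaves the
#' twitch-tetanus ratio unchanged). `gamma` and the Hill exponent are never
#' varied across units.
#'
#' @param target_ct_ms twitch contraction time target (ms)
#' @param target_tt twitch-tetanus ratio target
#' @param fiber_type `"slow"` or `"fast"`
#' @param perturb_sd log-scale SD of the per-unit perturbation of
#'   `alpha_S, k2, k3, k4i, K_hill, tau1` (0 disables)
#' @param dt integration step (s)
#' @param ct_tol,tt_tol relative tolerances checked after calibration
#' @return list with the calibrated `par`, achieved `ct_ms` and `tt`
#' @export
calibrate_unit <- function(target_ct_ms, target_tt,
                           fiber_type = c("slow", "fast"), perturb_sd = 0.1,
                           dt = 1e-4, ct_tol = 0.05, tt_tol = 0.10) {
  fiber_type <- match.arg(fiber_type)
  if (!is.finite(target_ct_ms) || target_ct_ms <= 0 ||
        !is.finite(target_tt) || target_tt <= 0 || target_tt >= 1)
    stop("calibration targets must be finite, with 0 < tt < 1")
  par <- seed_params(fiber_type)
  if (perturb_sd > 0) {
    pert <- c("alpha_S", "k2", "k3", "k4i", "K_hill", "tau1")
    par[pert] <- par[pert] * exp(rnorm(length(pert), 0, perturb_sd))
  }

  # twitch duration long enough for the slowest targets
  dur_tw <- max(0.8, 12 * target_ct_ms / 1000)

  f <- function(lk1) {
    p <- par
    p["k1"] <- exp(lk1)
    tryCatch(measure_tt(p, dt = dt) - target_tt, error = function(e) NA_real_)
  }
  # expand the bracket outward from the seed; the twitch-tetanus ratio is
  # monotone increasing in k1 over the usable range
  lk0 <- log(par[["k1"]])
  fc <- f(lk0)
  if (is.na(fc))
    stop("calibration failure: seed parameter set does not simulate")
  lo <- hi <- lk0
  flo <- fhi <- fc
  step <- log(2)
  for (it in 1:14) {
    if (flo > 0) {
      cand <- f(lo - step)
      if (!is.na(cand)) { lo <- lo - step; flo <- cand } else break
    }
    if (fhi < 0) {
      cand <- f(hi + step)
      if (!is.na(cand)) { hi <- hi + step; fhi <- cand } else break
    }
    if (flo <= 0 && fhi >= 0) break
  }
  if (!(flo <= 0 && fhi >= 0))
    stop(sprintf(
      "calibration failure: tt target %.3f not bracketed (achieved %.3f..%.3f)",
      target_tt, flo + target_tt, fhi + target_tt))
  root <- uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi, tol = 1e-3)
  par["k1"] <- exp(root$root)

  ct <- twitch_response(par, duration = dur_tw, dt = dt)$ct_ms
  par <- rescale_time(par, ct / target_ct_ms)

  tw <- twitch_response(par, duration = dur_tw, dt = dt)
  tt <- measure_tt(par, dt = dt)
  if (abs(tw$ct_ms - target_ct_ms) > ct_tol * target_ct_ms ||
        abs(tt - target_tt) > tt_tol * target_tt)
    stop(sprintf(
      "calibration failure: achieved CT %.2f ms (target %.2f), tt %.3f (target %.3f)",
      tw$ct_ms, target_ct_ms, tt, target_tt))
  list(par = par, ct_ms = tw$ct_ms, tt = tt)
}

#' Calibrate every unit of a pool
#'
#' Runs [calibrate_unit()] for each unit against its contraction-time and
#' twitch-tetanus targets, determines each unit's plateau activation and
#' `f0.5` empirically, and sets `MDR = 0.5 * f0.5`, `PDR = 2 * f0.5`
#' (onion-skin pools instead get the fixed 8 Hz / 35..25 Hz limits via
#' [apply_onion_skin()]). Seeded from the pool seed: identical pools calibrate
#' identically.
#'
#' @param pool a `mu_pool` from [build_pool()]
#' @param dt integration step for calibration (s)
#' @param perturb_sd per-unit parameter scatter (log-scale SD)
#' @param verbose print progress every 50 units
#' @return the calibrated pool (activation parameters joined to `units`)
#' @export
calibrate_pool <- function(pool, dt = 1e-4, perturb_sd = 0.1,
                           verbose = FALSE) {
  units <- pool$units
  n <- nrow(units)
  parmat <- matrix(NA_real_, n, length(act_par_names),
                   dimnames = list(NULL, act_par_names))
  f05 <- plateau <- numeric(n)
  withr_seed(pool$seed + 2L, {
    for (i in seq_len(n)) {
      cal <- calibrate_unit(units$CT_ms[i], units$tt_ratio[i],
                            as.character(units$fiber_type[i]),
                            perturb_sd = perturb_sd, dt = dt)
      parmat[i, ] <- cal$par[act_par_names]
      fr <- find_f0_5(cal$par, dt = dt)
      f05[i] <- fr$f0_5
      plateau[i] <- fr$plateau
      if (verbose && i %% 50 == 0)
        message(sprintf("calibrated %d/%d units", i, n))
    }
  })
  units$f0_5 <- f05
  units$plateau <- plateau
  units$MDR <- 0.5 * f05
  units$PDR <- 2 * f05
  pool$units <- cbind(units, as.data.frame(parmat))
  if (pool$recruitment_scheme == "onion_skin") pool <- apply_onion_skin(pool)
  pool$calibrated <- TRUE
  pool
}

# Extract the activation-parameter matrix from a calibrated pool.
pool_par_matrix <- function(pool) {
  stopifnot(isTRUE(pool$calibrated))
  as.matrix(pool$units[, act_par_names])
}

#' Hill stage of the activation cascade
#'
#' `A_tilde = x^N / (x^N + K^N)` with `x = cf * S * Y` (bound myofilament
#' fraction scaled by the sag and yield states). Strictly increasing in `x`,
#' 0 at 0, 1/2 at `x = K`, saturating at 1.
#'
#' @param cf bound myofilament fraction
#' @param S sag state (1 for slow units)
#' @param Y yield state (1 for fast units)
#' @param N_hill Hill exponent
#' @param K_hill half-saturation constant
#' @return intermediate activation in `[0, 1)`
#' @export
hill_stage <- function(cf, S = 1, Y = 1, N_hill, K_hill) {
  x <- pmax(cf * S * Y, 0)
  xn <- x^N_hill
  xn / (xn + K_hill^N_hill)
}

#' Length scaling of the activation parameters
#'
#' `x = phi * x0 * (1 - Lce) + x0` applied to `k3`, the Hill exponent, the
#' Hill half-saturation and `gamma`, with `phi_short` below optimal length and
#' `phi_long` above. Identity at `Lce = 1` or `phi = 0`. Scaled values are
#' floored at 1e-6 (the affine form can cross zero for large `phi`), with a
#' warning.
#'
#' @param par activation-parameter vector
#' @param Lce normalized fascicle length
#' @return the parameter vector with scaled `k3`, `N_hill`, `K_hill`, `gamma`
#' @export
length_scale_params <- function(par, Lce) {
  if (Lce <= 0) stop("Lce must be positive")
  phi <- if (Lce < 1) par[["phi_short"]] else par[["phi_long"]]
  if (phi == 0 || Lce == 1) return(par)
  for (f in c("k3", "N_hill", "K_hill", "gamma")) {
    x <- phi * par[[f]] * (1 - Lce) + par[[f]]
    if (x <= 1e-6) {
      warning("length-scaled ", f, " clamped at 1e-6")
      x <- 1e-6
    }
    par[f] <- x
  }
  par
}

#' Fit the length-dependence coefficients
#'
#' Scalar least-squares fit of `phi_short` (lengths 0.8 and 0.9) and
#' `phi_long` (1.1 and 1.2) to target activation-frequency curves: for each
#' candidate `phi` the model's mean-activation curve is simulated at the
#' target lengths and rates and compared to the target values. The same `phi`
#' scales all four length-dependent parameters.
#'
#' @param par calibrated activation-parameter vector
#' @param targets data.frame with columns `Lce`, `rate_hz`, `mean_activation`
#' @param interval search interval for `phi`
#' @param dt integration step (s)
#' @return `par` with fitted `phi_short`/`phi_long`
#' @export
fit_phi <- function(par, targets = NULL, interval = c(-3, 3), dt = 2e-4) {
  if (is.null(targets) || nrow(targets) == 0) {
    warning("no target activation-frequency curves supplied; phi set to 0")
    par[c("phi_short", "phi_long")] <- 0
    return(par)
  }
  sse_for <- function(phi, side) {
    p <- par
    p[if (side == "short") "phi_short" else "phi_long"] <- phi
    rows <- if (side == "short") targets$Lce < 1 else targets$Lce > 1
    tg <- targets[rows, ]
    pred <- vapply(seq_len(nrow(tg)), function(j)
      mean_activation_at(p, tg$rate_hz[j], dt = dt, Lce = tg$Lce[j]),
      numeric(1))
    sum((pred - tg$mean_activation)^2)
  }
  if (any(targets$Lce < 1))
    par["phi_short"] <- optimize(sse_for, interval, side = "short")$minimum
  if (any(targets$Lce > 1))
    par["phi_long"] <- optimize(sse_for, interval, side = "long")$minimum
  par
}
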