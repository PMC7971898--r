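# Simulation protocols and statistics: single-unit activation-frequency and
# fusion curves, ramp-and-hold population trials with the detrending recipes,
# power spectra, recruitment-pattern statistics and the sensitivity suite.

#' Ramp-and-hold trial protocol
#'
#' @param zero_s,ramp_s,hold_s phase durations (s)
#' @param analysis_s analysed tail of the hold phase (s)
#' @param n_trials trials per input level
#' @return list of class `trial_protocol`
#' @export
trial_protocol <- function(zero_s = 1, ramp_s = 2, hold_s = 13,
                           analysis_s = 10, n_trials = 10) {
  stopifnot(zero_s > 0, ramp_s > 0, hold_s > 0, analysis_s <= hold_s)
  structure(list(zero_s = zero_s, ramp_s = ramp_s, hold_s = hold_s,
                 analysis_s = analysis_s, n_trials = n_trials),
            class = "trial_protocol")
}

#' Degree of fusion of a tetanic response
#'
#' `(1 - p / Pt) * 100` where `p` is the peak-to-peak ripple of the signal
#' over the last second and `Pt` the single-twitch amplitude: 0% at the
#' twitch, 100% for a fully fused (flat) response.
#'
#' @param x signal (activation or force)
#' @param time sample times (s)
#' @param twitch_peak twitch amplitude `Pt`
#' @param window ripple window (s), taken from the end
#' @return fusion (%)
#' @export
fusion_degree <- function(x, time, twitch_peak, window = 1) {
  if (twitch_peak <= 0) stop("twitch amplitude must be positive")
  tail_x <- x[time >= max(time) - window]
  p <- max(tail_x) - min(tail_x)
  (1 - p / twitch_peak) * 100
}

#' Activation-frequency and fusion curve of one unit
#'
#' Stimulates an isolated unit (no series-elastic element) with 3-s periodic
#' trains, returning the mean activation over the last second and the degree
#' of fusion at each rate.
#'
#' @param par activation-parameter vector
#' @param rates stimulus rates (Hz)
#' @param Lce normalized fascicle length
#' @param dt integration step (s)
#' @param duration train duration (s)
#' @return data.frame with `rate_hz`, `mean_activation`, `fusion_pct`
#' @export
activation_frequency_curve <- function(par, rates, Lce = 1, dt = 1e-4,
                                       duration = 3) {
  pt <- twitch_response(par, dt = dt, Lce = Lce)$peak
  res <- lapply(rates, function(r) {
    tr <- simulate_activation(periodic_train(r, duration), par, duration, dt,
                              Lce)
    last <- tr$time >= duration - 1
    data.frame(rate_hz = r, mean_activation = mean(tr$A[last]),
               fusion_pct = fusion_degree(tr$A, tr$time, pt))
  })
  do.call(rbind, res)
}

#' Single-unit battery over the whole pool
#'
#' For every calibrated unit: mean activation (as % of its plateau) at
#' 0.5, 1.1 and 2 times `f0.5`, fusion at `1.1 * f0.5`, the rate multiple at
#' which fusion crosses 50% (linear interpolation over a multiples grid), and
#' the interspike interval at `f0.5` expressed in contraction times.
#'
#' @param pool a calibrated `mu_pool`
#' @param dt integration step (s)
#' @param multiples rate-multiple grid for the fusion crossing
#' @return data.frame, one row per unit
#' @export
unit_battery <- function(pool, dt = 1e-4,
                         multiples = c(0.4, 0.6, 0.8, 1.0, 1.2, 1.5)) {
  stopifnot(isTRUE(pool$calibrated))
  units <- pool$units
  parmat <- pool_par_matrix(pool)
  res <- lapply(seq_len(nrow(units)), function(i) {
    par <- parmat[i, ]
    f05 <- units$f0_5[i]
    plat <- units$plateau[i]
    pt <- twitch_response(par, dt = dt)$peak
    act_pct <- function(rate) 100 * mean_activation_at(par, rate, dt) / plat
    fus <- function(rate) {
      tr <- simulate_activation(periodic_train(rate, 3), par, 3, dt)
      fusion_degree(tr$A, tr$time, pt)
    }
    fgrid <- vapply(multiples * f05, fus, numeric(1))
    m50 <- if (all(fgrid < 50) || all(fgrid > 50)) NA_real_ else
      approx(fgrid, multiples, xout = 50, ties = "ordered")$y
    data.frame(index = units$index[i],
               act_at_0_5 = act_pct(0.5 * f05),
               act_at_1_1 = act_pct(1.1 * f05),
               act_at_2_0 = act_pct(2 * f05),
               fusion_at_1_1 = fus(1.1 * f05),
               mult_at_50_fusion = m50,
               isi_f05_over_ct = (1000 / f05) / units$CT_ms[i])
  })
  do.call(rbind, res)
}

# ---------------------------------------------------------------------------
# Population trials
# ---------------------------------------------------------------------------

# Remove a least-squares polynomial trend of the given order.
detrend <- function(x, order = 1) {
  t <- seq_along(x)
  stats::residuals(lm(x ~ poly(t, order)))
}

# Segment-wise detrended SD: split into n_seg equal segments, detrend each
# with a polynomial of the given order, average the per-segment SDs.
segmented_detrended_sd <- function(x, n_seg, order) {
  idx <- split(seq_along(x), cut(seq_along(x), n_seg, labels = FALSE))
  mean(vapply(idx, function(j) sd(detrend(x[j], order)), numeric(1)))
}

# Statistics of one analysed force segment: raw SD/CoV plus the two
# detrending recipes (ten 1-s segments with linear detrend over the last
# 10 s; two 4-s segments with 2nd-order detrend over the last 8 s). CoV
# denominators use the raw mean.
segment_stats <- function(force, fs) {
  m <- mean(force)
  sd_raw <- sd(force)
  n10 <- min(length(force), round(10 * fs))
  x10 <- tail(force, n10)
  sd_seg1 <- segmented_detrended_sd(x10, max(1, round(n10 / fs)), 1)
  n8 <- min(length(force), round(8 * fs))
  x8 <- tail(force, n8)
  sd_seg2 <- segmented_detrended_sd(x8, 2, 2)
  data.frame(mean = m, sd_raw = sd_raw, cov_raw = 100 * sd_raw / m,
             sd_detrend1 = sd_seg1, cov_detrend1 = 100 * sd_seg1 / m,
             sd_detrend2 = sd_seg2, cov_detrend2 = 100 * sd_seg2 / m)
}

#' Steady-state force-input curve
#'
#' Deterministic (zero discharge variability) short ramp-and-hold trials over
#' a grid of input levels; returns the steady tendon force per level and the
#' force as % of the force at maximal input.
#'
#' @param pool calibrated `mu_pool`
#' @param levels input levels (fractions of maximal input)
#' @param use_see include the series-elastic element
#' @param dt integration step (s)
#' @return data.frame with `ueff`, `force_n`, `force_pct`
#' @export
steady_force_curve <- function(pool, levels = c(0.025, 0.05, seq(0.1, 1, 0.1)),
                               use_see = TRUE, dt = 5e-4) {
  params <- rate_coding_params(cv_mode = "constant", cv_constant = 0)
  force <- vapply(levels, function(lv) {
    u <- ramp_hold_input(lv, dt, zero_s = 0.5, ramp_s = 1, hold_s = 2.5)
    tr <- simulate_trial(pool, u, dt, params, use_see = use_see, seed = 1)
    mean(tr$Fout[tr$time >= max(tr$time) - 1])
  }, numeric(1))
  fmax <- if (any(levels == 1)) force[levels == 1] else max(force)
  data.frame(ueff = levels, force_n = force, force_pct = 100 * force / fmax)
}

#' Ramp-and-hold population trials with variability statistics
#'
#' Runs seeded trials of the chosen model at each synaptic-input level and
#' summarizes the analysed tail of the hold phase: mean force, raw SD/CoV and
#' the two detrended recipes (ten 1-s linearly detrended segments; two 4-s
#' segments detrended with a 2nd-order polynomial). Per-unit force statistics
#' are returned for `keep_units`.
#'
#' @param pool calibrated `mu_pool` (ignored for `model = "fuglevand"`)
#' @param levels input levels (fractions of maximal input)
#' @param protocol a [trial_protocol()]
#' @param seed integer seed; trial `j` at level `k` uses
#'   `seed + 1000 * k + j`
#' @param params a [rate_coding_params()]
#' @param use_see include the series-elastic element
#' @param dt integration step (s)
#' @param model `"new"` or `"fuglevand"`
#' @param fug_pool a [fuglevand_pool()] when `model = "fuglevand"`
#' @param fug_cv ISI CoV (%) for the Fuglevand model
#' @param keep_units unit indices tracked individually (new model only)
#' @param return_traces keep the analysed force segment of every trial
#' @return list with `summary` (per level, averaged over trials), `trials`
#'   (per trial), `unit_stats`, and optionally `traces`
#' @export
run_population_protocol <- function(pool = NULL, levels,
                                    protocol = trial_protocol(), seed = 1,
                                    params = rate_coding_params(
                                      cv_mode = "input_dependent"),
                                    use_see = TRUE, dt = 5e-4,
                                    model = c("new", "fuglevand"),
                                    fug_pool = NULL, fug_cv = 10,
                                    keep_units = integer(0),
                                    return_traces = FALSE) {
  model <- match.arg(model)
  fs <- 1000
  trials <- list()
  unit_stats <- list()
  traces <- list()
  for (k in seq_along(levels)) {
    lv <- levels[k]
    for (j in seq_len(protocol$n_trials)) {
      trial_seed <- seed + 1000L * k + j
      if (model == "new") {
        u <- ramp_hold_input(lv, dt, protocol$zero_s, protocol$ramp_s,
                             protocol$hold_s)
        tr <- simulate_trial(pool, u, dt, params, use_see = use_see,
                             keep_units = keep_units, out_dt = 1 / fs,
                             seed = trial_seed)
      } else {
        if (is.null(fug_pool)) fug_pool <- fuglevand_pool()
        u <- ramp_hold_input(lv, 1e-3, protocol$zero_s, protocol$ramp_s,
                             protocol$hold_s)
        tr <- fuglevand_trial(fug_pool, u, 1e-3, cv = fug_cv,
                              seed = trial_seed)
      }
      sel <- tr$time >= max(tr$time) - protocol$analysis_s
      st <- segment_stats(tr$Fout[sel], fs)
      st$level <- lv
      st$trial <- j
      trials[[length(trials) + 1]] <- st
      if (length(keep_units) && model == "new") {
        uf <- tr$unit_force[sel, , drop = FALSE]
        unit_stats[[length(unit_stats) + 1]] <- data.frame(
          level = lv, trial = j, unit = keep_units,
          mean = colMeans(uf),
          sd = apply(uf, 2, sd),
          cov = 100 * apply(uf, 2, sd) / pmax(colMeans(uf), .Machine$double.eps)
        )
      }
      if (return_traces)
        traces[[sprintf("level%g_trial%d", lv, j)]] <-
          list(time = tr$time[sel], Fout = tr$Fout[sel],
               pool_spikes = tr$pool_spikes[sel])
    }
  }
  trials <- do.call(rbind, trials)
  summ <- do.call(rbind, lapply(split(trials, trials$level), function(d) {
    out <- as.data.frame(lapply(d[, !(names(d) %in% c("level", "trial"))],
                                mean))
    out$level <- d$level[1]
    out
  }))
  rownames(summ) <- NULL
  list(summary = summ[order(summ$level), ], trials = trials,
       unit_stats = if (length(unit_stats)) do.call(rbind, unit_stats),
       traces = if (return_traces) traces)
}

#' Power spectral density on a fixed 0.5 Hz grid
#'
#' Single-window (Hann) periodogram of the demeaned signal, with the native
#' frequency bins averaged onto a 0.5 Hz grid from 0 to `fmax` - no
#' segmentation, no overlap. Normalized so the integrated density matches the
#' signal variance (Parseval).
#'
#' @param x signal
#' @param fs sampling rate (Hz)
#' @param fmax upper frequency bound (Hz)
#' @param df grid resolution (Hz)
#' @return data.frame with `freq` (grid centers) and `power` (one-sided
#'   density, signal units squared per Hz)
#' @export
welch_psd <- function(x, fs, fmax = 100, df = 0.5) {
  n <- length(x)
  if (n < 4 * fs / df) stop("signal too short for the requested resolution")
  x <- x - mean(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)  # Hann
  X <- fft(x * w)
  pden <- (Mod(X)^2) / (fs * sum(w^2))              # two-sided density
  freq <- (seq_len(n) - 1) * fs / n
  half <- freq <= fs / 2
  pden <- pden[half] * 2                            # one-sided
  pden[1] <- pden[1] / 2
  freq <- freq[half]
  grid <- seq(df, fmax, by = df)
  bin <- findInterval(freq, c(grid - df / 2, fmax + df / 2))
  keep <- bin >= 1 & bin <= length(grid) & freq > 0
  power <- vapply(seq_along(grid), function(b) {
    v <- pden[keep & bin == b]
    if (length(v)) mean(v) else 0
  }, numeric(1))
  data.frame(freq = grid, power = power)
}

#' Integrated spectral power in a band
#'
#' @param psd a data.frame from [welch_psd()]
#' @param lo,hi band edges (Hz)
#' @return integrated power (signal units squared)
#' @export
band_power <- function(psd, lo, hi) {
  sel <- psd$freq >= lo & psd$freq <= hi
  sum(psd$power[sel]) * mean(diff(psd$freq))
}

#' Recruitment-pattern pair statistics
#'
#' Samples motor-unit pairs and reports the fraction in which the
#' higher-threshold unit also has the higher peak discharge rate (the
#' "reverse onion-skin" pattern), with an exact two-sided binomial test
#' against chance.
#'
#' @param pool calibrated `mu_pool`
#' @param n_pairs number of sampled pairs (without replacement)
#' @param seed integer seed
#' @param exhaustive use all `n*(n-1)/2` pairs instead of sampling
#' @return list with `fraction_reverse`, `p_value`, `n_pairs`
#' @export
onion_skin_pair_analysis <- function(pool, n_pairs = 1000, seed = 1,
                                     exhaustive = FALSE) {
  units <- pool$units
  n <- nrow(units)
  all_pairs <- utils::combn(n, 2)
  if (exhaustive) {
    sel <- seq_len(ncol(all_pairs))
  } else {
    sel <- withr_seed(seed, sample(ncol(all_pairs), n_pairs))
  }
  i <- all_pairs[1, sel]
  j <- all_pairs[2, sel]
  consistent <- sign(units$RT[j] - units$RT[i]) ==
    sign(units$PDR[j] - units$PDR[i])
  frac <- mean(consistent)
  bt <- binom.test(sum(consistent), length(consistent), p = 0.5)
  list(fraction_reverse = frac, p_value = bt$p.value,
       n_pairs = length(consistent))
}

#' Discharge-pattern correlations of the pool
#'
#' Pearson correlation between peak discharge rate and recruitment threshold
#' over all units, and between the discharge rate at a given submaximal input
#' and recruitment threshold over the units active at that input.
#'
#' @param pool calibrated `mu_pool`
#' @param ueff submaximal input level
#' @param params a [rate_coding_params()]
#' @return list with `r_pdr_rt`, `r_dr_rt`, `n_active`
#' @export
correlation_reports <- function(pool, ueff = 0.2,
                                params = rate_coding_params()) {
  units <- pool$units
  dr <- discharge_rate(pool, ueff, params)
  act <- dr > 0
  if (sum(act) < 3) stop("fewer than 3 active units at ueff = ", ueff)
  list(r_pdr_rt = cor(units$PDR, units$RT),
       r_dr_rt = cor(dr[act], units$RT[act]),
       n_active = sum(act))
}

#' Sensitivity suite
#'
#' Re-runs the population protocol under the six perturbed model variants:
#' no series-elastic element, peak-tetanic-force range 100, recruitment range
#' 0.5, pool size 100, onion-skin recruitment scheme, and all combined.
#'
#' @param base_muscle baseline [muscle_config()]
#' @param levels input levels
#' @param protocol a [trial_protocol()]
#' @param seed integer seed
#' @param params a [rate_coding_params()]
#' @param dt integration step (s)
#' @param scenarios subset of scenario names to run
#' @return named list of `run_population_protocol()` results plus each
#'   scenario's simulated maximal force
#' @export
sensitivity_suite <- function(base_muscle = muscle_config(), levels,
                              protocol = trial_protocol(), seed = 1,
                              params = rate_coding_params(
                                cv_mode = "input_dependent"),
                              dt = 5e-4,
                              scenarios = c("base", "no_see", "rp100",
                                            "ur05", "n100", "onion_skin",
                                            "combined")) {
  mk <- function(m, ...) {
    args <- utils::modifyList(unclass(m), list(...))
    do.call(muscle_config, args[names(args) %in% names(formals(muscle_config))])
  }
  defs <- list(
    base = list(muscle = base_muscle, use_see = TRUE, scheme = "new_scheme"),
    no_see = list(muscle = base_muscle, use_see = FALSE, scheme = "new_scheme"),
    rp100 = list(muscle = mk(base_muscle, rp = 100), use_see = TRUE,
                 scheme = "new_scheme"),
    ur05 = list(muscle = mk(base_muscle, ur = 0.5), use_see = TRUE,
                scheme = "new_scheme"),
    n100 = list(muscle = mk(base_muscle, n_units = 100L), use_see = TRUE,
                scheme = "new_scheme"),
    onion_skin = list(muscle = base_muscle, use_see = TRUE,
                      scheme = "onion_skin"),
    combined = list(muscle = mk(base_muscle, rp = 100, ur = 0.5,
                                n_units = 100L), use_see = FALSE,
                    scheme = "onion_skin")
  )
  out <- list()
  for (nm in scenarios) {
    d <- defs[[nm]]
    res <- tryCatch({
      pool <- calibrate_pool(build_pool(d$muscle, seed = seed,
                                        recruitment_scheme = d$scheme))
      run <- run_population_protocol(pool, levels, protocol, seed = seed,
                                     params = params, use_see = d$use_see,
                                     dt = dt)
      fmax <- steady_force_curve(pool, levels = 1, use_see = d$use_see,
                                 dt = dt)$force_n
      run$fmax <- fmax
      run
    }, error = function(e) {
      warning("scenario '", nm, "' failed: ", conditionMessage(e))
      NULL
    })
    out[[nm]] <- res
  }
  out
}
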