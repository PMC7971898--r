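# Reference models: the Fuglevand twitch-summation pool (kept with its
# original behavior, defects included) and the second-order
# signal-dependent-noise filter used in optimal-control models, plus the
# empirical SD-mean power law they are compared against.

#' Build a Fuglevand-style motor unit pool
#'
#' Peak twitch forces span a 100-fold exponential range, contraction times a
#' 3-fold range tied to twitch force (`T_i = T_max * (1/P_i)^(1/c)` with
#' `c = log(RP)/log(RT)`), and recruitment-threshold excitations an
#' exponential `rte_range`-fold range with recruitment complete at 80% of
#' maximal excitation (`E_max = RTE_n / 0.8`). All units start at 8 Hz; peak
#' rates fall linearly from 35 Hz (smallest unit) to 25 Hz (largest); the
#' excitation-rate gain is 1 for every unit.
#'
#' @param n number of units
#' @param p_range fold-range of peak twitch force
#' @param t_range fold-range of contraction time
#' @param t_max longest contraction time (ms)
#' @param rte_range fold-range of recruitment-threshold excitation
#' @param recruit_at fraction of maximal excitation at which the last unit is
#'   recruited
#' @param mfr,pfr1,pfrd minimal firing rate, peak rate of the first unit, and
#'   the total peak-rate drop across the pool (Hz)
#' @return data.frame of class `fuglevand_pool`
#' @export
fuglevand_pool <- function(n = 120, p_range = 100, t_range = 3, t_max = 90,
                           rte_range = 68, recruit_at = 0.8, mfr = 8,
                           pfr1 = 35, pfrd = 10) {
  i <- seq_len(n)
  P <- exp(log(p_range) * i / n)
  Tms <- t_max * (1 / P)^(1 / (log(p_range) / log(t_range)))
  RTE <- exp(log(rte_range) * i / n)
  Emax <- RTE[n] / recruit_at
  PFR <- pfr1 - pfrd * RTE / RTE[n]
  pool <- data.frame(index = i, P = P, T_ms = Tms, RTE = RTE, MFR = mfr,
                     PFR = PFR)
  attr(pool, "Emax") <- Emax
  class(pool) <- c("fuglevand_pool", "data.frame")
  pool
}

# Sigmoidal gain of the twitch-summation model: 1 for normalized stimulus
# rate T/ISI <= 0.4, otherwise S(x)/x scaled to be continuous at 0.4,
# S(x) = 1 - exp(-2 x^3).
fuglevand_gain <- function(t_over_isi) {
  s <- function(x) 1 - exp(-2 * x^3)
  ref <- s(0.4) / 0.4
  ifelse(t_over_isi <= 0.4, 1, (s(t_over_isi) / t_over_isi) / ref)
}

#' Force of one Fuglevand unit for a given spike train
#'
#' Superposition of gain-scaled critically damped impulse responses
#' `g * P * (t/T) * exp(1 - t/T)`; the gain follows the sigmoidal
#' rate-dependence of the original model (1 for the first spike of a train).
#' The two-state linear filter update is exact per step, so this matches the
#' per-spike convolution to machine precision.
#'
#' @param spike_times sorted spike times (s)
#' @param P peak twitch force (arbitrary units)
#' @param T_ms contraction time (ms)
#' @param duration trace duration (s)
#' @param dt output step (s)
#' @return force trace sampled every `dt` starting at t = 0
#' @export
fuglevand_unit_force <- function(spike_times, P, T_ms, duration, dt = 1e-3) {
  Tsec <- T_ms / 1000
  nt <- round(duration / dt)
  out <- numeric(nt + 1)
  spike_times <- sort(spike_times)
  isi_prev <- c(Inf, diff(spike_times))
  gains <- fuglevand_gain(Tsec / isi_prev)
  mag <- gains * P * exp(1) / Tsec
  ks <- pmin(floor(spike_times / dt) + 1, nt)
  d <- exp(-dt / Tsec)
  e <- 0; x <- 0
  si <- 1; ns <- length(spike_times)
  for (k in seq_len(nt)) {
    while (si <= ns && ks[si] == k) {
      e <- e + mag[si]
      si <- si + 1
    }
    x <- d * (x + e * dt)
    e <- d * e
    out[k + 1] <- x
  }
  out
}

# Discharge rate of a Fuglevand unit at excitation E (excitation units).
fuglevand_rate <- function(pool, E) {
  dr <- pmin(pool$MFR + (E - pool$RTE), pool$PFR)
  dr[E < pool$RTE] <- 0
  dr
}

#' Simulate one Fuglevand population trial
#'
#' Generates renewal spike trains (same truncated-Gaussian ISI model as the
#' main pool) for every unit at the excitation level given by the synaptic
#' input trajectory, and sums the twitch trains. Output in the model's
#' arbitrary force units.
#'
#' @param pool a [fuglevand_pool()]
#' @param ueff synaptic input trajectory in `[0, 1]` sampled every `dt`
#'   (scaled internally to excitation units)
#' @param dt step (s)
#' @param cv CoV of interspike intervals (%)
#' @param seed optional seed
#' @return list with `time`, `Fout`, `n_spikes`
#' @export
fuglevand_trial <- function(pool, ueff, dt = 1e-3, cv = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Emax <- attr(pool, "Emax")
  nt <- length(ueff)
  duration <- nt * dt
  n <- nrow(pool)
  total <- numeric(nt)
  nsp <- integer(n)
  for (i in seq_len(n)) {
    spikes <- numeric(0)
    t <- 0
    repeat {
      k <- min(floor(t / dt) + 1, nt)
      E <- ueff[k] * Emax
      if (E < pool$RTE[i]) {
        t <- t + dt
        if (t >= duration) break
        next
      }
      dr <- pool$MFR[i] + (E - pool$RTE[i])
      dr <- min(dr, pool$PFR[i])
      spikes <- c(spikes, t)
      mu <- 1 / dr
      repeat {
        isi <- mu * (1 + cv * rtruncnorm39() / 100)
        if (isi > 0) break
      }
      t <- t + isi
      if (t >= duration) break
    }
    nsp[i] <- length(spikes)
    if (length(spikes))
      total <- total + fuglevand_unit_force(spikes, pool$P[i], pool$T_ms[i],
                                            duration, dt)[seq_len(nt)]
  }
  list(time = seq(0, by = dt, length.out = nt), Fout = total, n_spikes = nsp)
}

#' Second-order signal-dependent-noise filter
#'
#' `tau1 * tau2 * f'' + (tau1 + tau2) * f' + f = u_t * (1 + sigma_c * eps_t)`
#' with `eps_t` i.i.d. standard normal per step, integrated by the forward
#' Euler scheme at the model's own step (10 ms).
#'
#' @param u input amplitude in `(0, 1]`
#' @param sigma_c multiplicative noise scale
#' @param tau1,tau2 filter time constants (s)
#' @param dt step (s)
#' @param duration trial duration (s)
#' @param seed optional seed
#' @return list with `time` and `f`
#' @export
todorov_trial <- function(u, sigma_c = 0.5, tau1 = 0.04, tau2 = 0.04,
                          dt = 0.01, duration = 15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nt <- round(duration / dt)
  f <- numeric(nt + 1)
  fd <- 0
  for (k in seq_len(nt)) {
    input <- u * (1 + sigma_c * rnorm(1))
    fdd <- (input - f[k] - (tau1 + tau2) * fd) / (tau1 * tau2)
    fd <- fd + dt * fdd
    f[k + 1] <- f[k] + dt * fd
  }
  list(time = seq(0, by = dt, length.out = nt + 1), f = f)
}

#' Slope of the SD-input relationship of the noise filter
#'
#' Runs `n_trials` trials per input level, takes the SD of the last
#' `analysis_s` seconds of each, averages per level and fits a first-degree
#' polynomial through the (input, SD) points.
#'
#' @param u_levels input amplitudes
#' @param n_trials trials per level
#' @param analysis_s analysed tail duration (s)
#' @inheritParams todorov_trial
#' @return list with `slope`, `intercept` and the per-level table
#' @export
todorov_sd_slope <- function(u_levels = seq(0.1, 1, by = 0.1), n_trials = 10,
                             sigma_c = 0.5, tau1 = 0.04, tau2 = 0.04,
                             dt = 0.01, duration = 15, analysis_s = 10,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sds <- vapply(u_levels, function(u) {
    mean(vapply(seq_len(n_trials), function(j) {
      tr <- todorov_trial(u, sigma_c, tau1, tau2, dt, duration)
      sd(tr$f[tr$time >= duration - analysis_s])
    }, numeric(1)))
  }, numeric(1))
  fit <- lm(sds ~ u_levels)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       table = data.frame(u = u_levels, sd = sds))
}

#' Empirical signal-dependent-noise curve
#'
#' `SD(mean) = c * mean^p` with the exponent `p = 1.05` and the coefficient
#' solved from `SD(100%) = 2.34%` (percent of maximal voluntary force on both
#' axes).
#'
#' @param mean_pct mean force levels (% of maximum), in `(0, 100]`
#' @param p power-law exponent
#' @param sd_at_100 SD at 100% MVC (% of maximum)
#' @return SD values (% of maximum)
#' @export
jones_sd_curve <- function(mean_pct, p = 1.05, sd_at_100 = 2.34) {
  if (any(mean_pct <= 0 | mean_pct > 100)) stop("levels must lie in (0, 100]")
  cc <- sd_at_100 / 100^p
  cc * mean_pct^p
}
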