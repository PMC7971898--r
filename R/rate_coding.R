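# Rate coding: effective synaptic input -> discharge rates -> stochastic
# spike trains. Low-threshold units (RT below the cutoff) accelerate steeply
# upon recruitment and saturate; higher-threshold units increase their rate
# linearly up to PDR at maximal input.

#' Rate-coding parameters
#'
#' @param f_t transition frequency in units of `f0.5` at which low-threshold
#'   units switch from the steep to the shallow linear region
#' @param low_threshold_cutoff recruitment threshold below which the
#'   saturating (bilinear) scheme applies
#' @param cv_mode `"constant"` or `"input_dependent"` discharge variability
#' @param cv_constant CoV of interspike intervals (%) under `"constant"`
#' @param cv_a,cv_b,cv_c constants of the input-dependent CoV law
#'   `cv = a + b * exp(-(Ueff - RT) * 100 / c)` (input expressed in percent)
#' @return list of class `rate_coding_params`
#' @export
rate_coding_params <- function(f_t = 1.1, low_threshold_cutoff = 0.1,
                               cv_mode = c("constant", "input_dependent"),
                               cv_constant = 10, cv_a = 10, cv_b = 20,
                               cv_c = 2.5) {
  cv_mode <- match.arg(cv_mode)
  if (f_t <= 1) stop("f_t must exceed 1")
  if (cv_constant < 0) stop("cv_constant must be >= 0")
  structure(list(f_t = f_t, low_threshold_cutoff = low_threshold_cutoff,
                 cv_mode = cv_mode, cv_constant = cv_constant, cv_a = cv_a,
                 cv_b = cv_b, cv_c = cv_c), class = "rate_coding_params")
}

# Per-unit rate-coding constants. For the bilinear (saturating) scheme:
#   lambda = -100 * RT + 21
#   ke     = (ft*f05 - MDR + lambda * (PDR - ft*f05)) / (lambda * (1 - RT))
#   Ut     = 1 - (PDR - ft*f05) / ke
# The steep region has slope lambda*ke, the shallow region slope ke, and the
# two branches meet at DR = ft * f05 when Ueff = Ut. Units for which the
# bilinear form is infeasible (Ut outside (RT, 1) or non-positive slopes)
# fall back to the linear form. Returns a matrix consumed by both the R
# discharge-rate function and the C++ trial simulator.
rate_coding_table <- function(units, params = rate_coding_params()) {
  n <- nrow(units)
  RT <- units$RT
  MDR <- units$MDR
  PDR <- units$PDR
  f05 <- units$f0_5
  if (anyNA(MDR) || anyNA(f05))
    stop("pool is not calibrated: MDR/PDR/f0.5 missing (run calibrate_pool)")
  ft <- params$f_t
  scheme <- integer(n)
  ge <- (PDR - MDR) / (1 - RT)
  lambda <- -100 * RT + 21
  ke <- (ft * f05 - MDR + lambda * (PDR - ft * f05)) / (lambda * (1 - RT))
  Ut <- 1 - (PDR - ft * f05) / ke
  ok <- RT <= params$low_threshold_cutoff &
    MDR < ft * f05 & PDR > ft * f05 &
    is.finite(ke) & ke > 0 & lambda * ke > 0 & Ut > RT & Ut < 1
  scheme[ok] <- 1L
  cbind(RT = RT, MDR = MDR, PDR = PDR, f05 = f05, scheme = scheme, ge = ge,
        lamke = lambda * ke, ke = ke, Ut = Ut)
}

#' Discharge rate of each unit at a given synaptic input
#'
#' Returns 0 below recruitment threshold. High-threshold units increase
#' linearly from MDR at recruitment to PDR at maximal input; low-threshold
#' units (threshold below the cutoff) follow the continuous bilinear form with
#' a steep initial slope and saturation toward PDR.
#'
#' @param pool a calibrated `mu_pool` (see [calibrate_pool()])
#' @param ueff effective synaptic input, scalar in `[0, 1]`
#' @param params a [rate_coding_params()]
#' @return vector of discharge rates (Hz), one per unit
#' @export
discharge_rate <- function(pool, ueff, params = rate_coding_params()) {
  if (ueff < 0 || ueff > 1) stop("ueff must lie in [0, 1]")
  tab <- rate_coding_table(pool$units, params)
  discharge_rate_from_table(tab, ueff)
}

discharge_rate_from_table <- function(tab, ueff) {
  dr <- numeric(nrow(tab))
  act <- ueff >= tab[, "RT"]
  lin <- act & tab[, "scheme"] == 0
  bil <- act & tab[, "scheme"] == 1
  dr[lin] <- tab[lin, "MDR"] + tab[lin, "ge"] * (ueff - tab[lin, "RT"])
  steep <- bil & ueff <= tab[, "Ut"]
  shal <- bil & ueff > tab[, "Ut"]
  dr[steep] <- tab[steep, "MDR"] + tab[steep, "lamke"] * (ueff - tab[steep, "RT"])
  dr[shal] <- tab[shal, "PDR"] - tab[shal, "ke"] * (1 - ueff)
  pmin(dr, tab[, "PDR"])
}

#' Onion-skin discharge-rate limits
#'
#' Replaces the calibrated discharge-rate limits by the conventional
#' onion-skin scheme: every unit starts discharging at 8 Hz and peak rates
#' decrease linearly with unit index from 35 Hz (smallest unit) to 25 Hz
#' (largest). Units whose new MDR exceeds the bilinear transition frequency or
#' whose new PDR falls below `1.1 * f0.5` revert to the plain linear scheme
#' (that check is applied in [rate_coding_table()]).
#'
#' @param pool a calibrated `mu_pool`
#' @return the pool with onion-skin `MDR`/`PDR` and scheme flag set
#' @export
apply_onion_skin <- function(pool) {
  n <- nrow(pool$units)
  pool$units$MDR <- rep(8, n)
  pool$units$PDR <- 35 - 10 * (seq_len(n) - 1) / (n - 1)
  pool$recruitment_scheme <- "onion_skin"
  pool
}

# CoV of interspike intervals (%): constant, or the input-dependent
# exponential decline from (a + b) at recruitment toward a.
isi_cv <- function(ueff, RT, params) {
  if (params$cv_mode == "constant") return(rep(params$cv_constant, length(RT)))
  params$cv_a + params$cv_b * exp(-(ueff - RT) * 100 / params$cv_c)
}

# Standard normal truncated to [-3.9, 3.9] by rejection.
rtruncnorm39 <- function() {
  repeat {
    z <- rnorm(1)
    if (abs(z) <= 3.9) return(z)
  }
}

#' Generate a stochastic spike train for one unit
#'
#' Renewal process: each interspike interval is `mu * (1 + cv * Z / 100)` with
#' `mu = 1/DR` evaluated at the synaptic input at the previous spike and `Z`
#' standard normal truncated to `[-3.9, 3.9]` (redrawn in the rare case the
#' interval comes out non-positive). The unit is silent while the input is
#' below its recruitment threshold; the first spike falls exactly at the
#' threshold crossing.
#'
#' @param unit one row of a calibrated pool's `units` table
#' @param ueff_fun function of time returning the effective synaptic input
#' @param duration train duration (s)
#' @param params a [rate_coding_params()]
#' @param dt time resolution used to locate threshold crossings (s)
#' @return sorted numeric vector of spike times (s)
#' @export
generate_spike_train <- function(unit, ueff_fun, duration,
                                 params = rate_coding_params(), dt = 1e-3) {
  tab <- rate_coding_table(unit, params)
  spikes <- numeric(0)
  t <- 0
  active <- FALSE
  while (t < duration) {
    ue <- ueff_fun(t)
    if (!active) {
      if (ue >= unit$RT) {
        active <- TRUE
      } else {
        t <- t + dt
        next
      }
    } else if (ue < unit$RT) {
      active <- FALSE
      t <- t + dt
      next
    }
    dr <- discharge_rate_from_table(tab, ue)
    if (dr <= 0) {
      t <- t + dt
      next
    }
    spikes <- c(spikes, t)
    mu <- 1 / dr
    cv <- isi_cv(ue, unit$RT, params)
    repeat {
      isi <- mu * (1 + cv * rtruncnorm39() / 100)
      if (isi > 0) break
    }
    t <- t + isi
  }
  spikes
}

#' Mean discharge rate of active units across force levels
#'
#' Maps target force levels (% of maximal force) to synaptic input by inverse
#' interpolation of a simulated steady-state force-input curve, then averages
#' the discharge rate of all active units at each mapped input.
#'
#' @param pool a calibrated `mu_pool`
#' @param force_levels force levels, % of maximal force
#' @param force_input_curve data.frame with columns `ueff` and `force_pct`
#'   (a steady-state force-input relationship, e.g. from
#'   [steady_force_curve()])
#' @param params a [rate_coding_params()]
#' @return data.frame with `force_pct`, `ueff`, `mean_dr`, `n_active`
#' @export
mean_rate_profile <- function(pool, force_levels, force_input_curve,
                              params = rate_coding_params()) {
  if (any(force_levels < min(force_input_curve$force_pct) |
            force_levels > max(force_input_curve$force_pct)))
    stop("force level outside the simulated range")
  ue <- approx(force_input_curve$force_pct, force_input_curve$ueff,
               xout = force_levels, ties = "ordered")$y
  tab <- rate_coding_table(pool$units, params)
  res <- lapply(seq_along(ue), function(k) {
    dr <- discharge_rate_from_table(tab, ue[k])
    act <- dr > 0
    data.frame(force_pct = force_levels[k], ueff = ue[k],
               mean_dr = mean(dr[act]), n_active = sum(act))
  })
  do.call(rbind, res)
}

#' Write spike trains as tab-separated text
#'
#' One line per spike: `unit_id<TAB>time_s`.
#'
#' @param trains list of numeric spike-time vectors, one per unit
#' @param path output file
#' @export
write_spike_trains <- function(trains, path) {
  df <- data.frame(
    unit_id = rep(seq_along(trains), lengths(trains)),
    time_s = unlist(trains, use.names = FALSE)
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
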