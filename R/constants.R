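# Model constants: muscle architecture defaults, Hill-curve and passive-curve
# coefficients (Brown/Cheng "virtual muscle" forms, cat data, fiber-type
# resolved), sag/yield constants, and the slow/fast seed parameter sets from
# which per-unit activation dynamics are calibrated.

#' Default tibialis anterior muscle configuration
#'
#' Architectural and pool-level constants of the modelled muscle: mass,
#' optimal fascicle and tendon lengths, pennation angle, density, specific
#' tension, pool size, the fold-range of peak tetanic force, the recruitment
#' threshold range and the fraction of maximal force contributed by
#' slow-twitch units.
#'
#' @param muscle_mass muscle mass (g)
#' @param Lce0 optimal fascicle length (cm)
#' @param Lse0 optimal tendon (series-elastic) length (cm)
#' @param pennation pennation angle (degrees)
#' @param density muscle density (g/cm^3)
#' @param specific_tension specific tension (N/cm^2)
#' @param n_units number of motor units in the pool
#' @param rp fold-range of peak tetanic force (largest/smallest)
#' @param u1 recruitment threshold of the first unit (fraction of maximal
#'   synaptic input)
#' @param ur recruitment threshold of the last unit (fraction of maximal
#'   synaptic input)
#' @param slow_force_fraction fraction of maximal muscle force produced by
#'   slow-twitch units
#' @param ct_min,ct_max bounds of the contraction-time distribution (ms)
#' @param tt_mean,tt_min,tt_max pool mean and bounds of the twitch-tetanus
#'   ratio
#' @param tt_corr_slow,tt_corr_fast target within-type correlation between
#'   twitch-tetanus ratio and contraction time
#' @return a list of class `muscle_config`
#' @export
muscle_config <- function(muscle_mass = 150, Lce0 = 6.8, Lse0 = 27.5,
                          pennation = 9.6, density = 1.06,
                          specific_tension = 31.8, n_units = 200L, rp = 25,
                          u1 = 0.01, ur = 0.8, slow_force_fraction = 0.4,
                          ct_min = 20, ct_max = 85, tt_mean = 0.23,
                          tt_min = 0.07, tt_max = 0.53,
                          tt_corr_slow = 0.638, tt_corr_fast = 0.704) {
  cfg <- list(muscle_mass = muscle_mass, Lce0 = Lce0, Lse0 = Lse0,
              pennation = pennation, density = density,
              specific_tension = specific_tension,
              n_units = as.integer(n_units), rp = rp, u1 = u1, ur = ur,
              slow_force_fraction = slow_force_fraction, ct_min = ct_min,
              ct_max = ct_max, tt_mean = tt_mean, tt_min = tt_min,
              tt_max = tt_max, tt_corr_slow = tt_corr_slow,
              tt_corr_fast = tt_corr_fast)
  validate_muscle_config(cfg)
  class(cfg) <- "muscle_config"
  cfg
}

validate_muscle_config <- function(cfg) {
  num <- c("muscle_mass", "Lce0", "Lse0", "pennation", "density",
           "specific_tension", "rp")
  for (f in num)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop("muscle_config: '", f, "' must be positive", call. = FALSE)
  if (cfg$n_units < 2) stop("muscle_config: need at least 2 units", call. = FALSE)
  if (cfg$rp <= 1) stop("muscle_config: rp must exceed 1", call. = FALSE)
  if (!(cfg$u1 > 0 && cfg$u1 < cfg$ur && cfg$ur <= 1))
    stop("muscle_config: need 0 < u1 < ur <= 1", call. = FALSE)
  if (!(cfg$slow_force_fraction > 0 && cfg$slow_force_fraction < 1))
    stop("muscle_config: slow_force_fraction must lie in (0,1)", call. = FALSE)
  if (cfg$ct_min >= cfg$ct_max)
    stop("muscle_config: ct_min must be below ct_max", call. = FALSE)
  if (!(cfg$tt_min < cfg$tt_mean && cfg$tt_mean < cfg$tt_max))
    stop("muscle_config: need tt_min < tt_mean < tt_max", call. = FALSE)
  invisible(cfg)
}

# --- force-length / force-velocity / passive / tendon curve constants -------
# Logistic/exponential forms and cat-derived coefficients from the
# Brown/Cheng "virtual muscle" family (cat data). Lengths normalized to optimal
# fascicle (tendon) length, velocities to optimal fascicle lengths per second,
# forces to F0.
mt_curve_constants <- function() {
  list(
    fl_slow = c(beta = 2.30, omega = 1.12, rho = 1.62),
    fl_fast = c(beta = 1.55, omega = 0.75, rho = 2.12),
    # fv: vmax, cv0, cv1 (shortening); av0, av1, av2, bv (lengthening)
    fv_slow = c(vmax = -7.88, cv0 = 5.88, cv1 = 0, av0 = -4.70, av1 = 8.41,
                av2 = -5.34, bv = 0.35),
    fv_fast = c(vmax = -9.15, cv0 = -5.70, cv1 = 9.18, av0 = -1.53, av1 = 0,
                av2 = 0, bv = 0.69),
    se = c(c = 27.8, k = 0.0047, Lr = 0.964),
    pe1 = c(c = 23.0, k = 0.046, Lr = 1.17, Lmax = 1.1, eta = 0.001),
    pe2 = c(c = -0.02, k = -18.7, Lr = 0.79)
  )
}

# Sag (fast units) and yield (slow units) constants. a_S1 and T_S follow the
# population model's calibration (20 and 15 ms); a_S2 and the yield constants
# follow the Song et al. musculotendon model they were taken from.
sag_yield_constants <- function() {
  list(aS1 = 20, aS2 = 0.96, TS = 0.015, cY = 0.35, VY = 0.1, TY = 0.2)
}

# --- seed activation-parameter sets -----------------------------------------
# One canonical parameter set per fiber type. These are implementation
# constants constructed so that (i) a single twitch is unimodal with a
# physiological contraction time, (ii) the activation-frequency curve is
# sigmoidal and monotone with the reported anchors (about 16% of maximum at
# 0.5*f0.5, about 57% at 1.1*f0.5, about 85% at 2*f0.5), (iii) fusion reaches
# about 75% at 1.1*f0.5, and (iv) the interspike interval at f0.5 is about
# 1.18 contraction times. Per-unit parameters are derived from these seeds by
# calibrate_unit(). Order must match the C++ integrator.
act_par_names <- c("alpha_S", "alpha_C", "k1", "k2", "k3", "k4i", "gamma",
                   "N_hill", "K_hill", "tau1", "tau2", "tau3", "phi_short",
                   "phi_long", "fiber")

seed_params <- function(fiber_type = c("slow", "fast")) {
  fiber_type <- match.arg(fiber_type)
  p <- c(alpha_S = 9.428, alpha_C = 1.8, k1 = 19.7, k2 = 7.567,
         k3 = 197.51, k4i = 26.316, gamma = 0.8, N_hill = 4.481,
         K_hill = 0.287, tau1 = 0.00359, tau2 = 0.0381, tau3 = 0.16867,
         phi_short = 0, phi_long = 0, fiber = 0)
  if (fiber_type == "fast") {
    # the fast seed is the slow seed on a 3x faster clock (natural twitch
    # contraction time ~45 ms instead of ~136 ms)
    p <- rescale_time(p, 3)
    p["fiber"] <- 1
  }
  p
}
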