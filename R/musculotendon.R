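# Musculotendon mechanics: Hill-type contractile element in series with a
# tendon/aponeurosis (series-elastic element), externally isometric
# (constant musculotendon length). Curve evaluation lives in C++ (shared with
# the trial integrator); these wrappers expose them and the mechanics step.

#' Force-length and force-velocity scaling factors
#'
#' `force_length`: `FL = exp(-|((Lce^beta) - 1) / omega|^rho)`, peaking at 1
#' at optimal length. `force_velocity`: Hill hyperbola for shortening
#' (`Vce <= 0`), Katz-type curve for lengthening (`Vce > 0`), continuous with
#' value 1 at zero velocity.
#'
#' @param Lce normalized fascicle length
#' @param Vce normalized fascicle velocity (optimal lengths per second,
#'   shortening negative)
#' @param fiber_type `"slow"` or `"fast"` constants
#' @return scaling factor(s)
#' @export
force_length <- function(Lce, fiber_type = c("slow", "fast")) {
  fiber_type <- match.arg(fiber_type)
  k <- mt_curve_constants()[[paste0("fl_", fiber_type)]]
  fl_cpp(Lce, k[["beta"]], k[["omega"]], k[["rho"]])
}

#' @rdname force_length
#' @export
force_velocity <- function(Lce, Vce, fiber_type = c("slow", "fast")) {
  fiber_type <- match.arg(fiber_type)
  k <- mt_curve_constants()[[paste0("fv_", fiber_type)]]
  fv_cpp(rep_len(Lce, length(Vce)), Vce, k[["vmax"]], k[["cv0"]], k[["cv1"]],
         k[["av0"]], k[["av1"]], k[["av2"]], k[["bv"]])
}

#' Passive and tendon force curves (normalized to F0)
#'
#' `tendon_force`: series-elastic force vs normalized tendon length.
#' `passive_force_pe1`: parallel-elastic resistance to stretch (plus a small
#' viscous term). `passive_force_pe2`: passive resistance to shortening,
#' non-positive, ~0 above `Lce ~ 0.8`.
#'
#' @param Lse normalized tendon length
#' @param Lce normalized fascicle length
#' @param Vce normalized fascicle velocity
#' @return normalized force(s)
#' @export
tendon_force <- function(Lse) {
  k <- mt_curve_constants()$se
  fse_cpp(Lse, k[["c"]], k[["k"]], k[["Lr"]])
}

#' @rdname tendon_force
#' @export
passive_force_pe1 <- function(Lce, Vce = 0) {
  k <- mt_curve_constants()$pe1
  fpe1_cpp(Lce, rep_len(Vce, length(Lce)), k[["c"]], k[["k"]], k[["Lr"]],
           k[["Lmax"]], k[["eta"]])
}

#' @rdname tendon_force
#' @export
passive_force_pe2 <- function(Lce) {
  k <- mt_curve_constants()$pe2
  fpe2_cpp(Lce, k[["c"]], k[["k"]], k[["Lr"]])
}

#' Total contractile-element force
#'
#' `Fce = sum_i PT_i * A_i * (FL_i * FV_i + Fpe2)` with fiber-type-resolved
#' force-length and force-velocity factors; the passive shortening resistance
#' enters inside the activation-scaled per-unit term.
#'
#' @param pool a `mu_pool`
#' @param A activation vector aligned with the pool's unit order
#' @param Lce,Vce shared fascicle state
#' @return contractile force (N)
#' @export
contractile_force <- function(pool, A, Lce, Vce = 0) {
  stopifnot(length(A) == nrow(pool$units))
  fp2 <- passive_force_pe2(Lce)
  slow <- pool$units$fiber_type == "slow"
  gain_s <- force_length(Lce, "slow") * force_velocity(Lce, Vce, "slow") + fp2
  gain_f <- force_length(Lce, "fast") * force_velocity(Lce, Vce, "fast") + fp2
  sum(pool$units$PT[slow] * A[slow]) * gain_s +
    sum(pool$units$PT[!slow] * A[!slow]) * gain_f
}

# Mechanics constants in SI units plus curve coefficients, as consumed by the
# C++ trial integrator. Lmt is fixed so the passive equilibrium sits at
# Lce = 1 (optimal fascicle length at rest).
mech_constants <- function(muscle, F0 = compute_F0(muscle)) {
  k <- mt_curve_constants()
  a <- muscle$pennation * pi / 180
  Lce0 <- muscle$Lce0 / 100
  Lse0 <- muscle$Lse0 / 100
  # resting tendon length: Fse(Lse) = Fpe1(1) * cos(alpha)
  target <- passive_force_pe1(1, 0) * cos(a)
  lse_rest <- uniroot(function(l) tendon_force(l) - target, c(0.5, 1.2),
                      tol = 1e-12)$root
  list(F0 = F0, Mm_kg = muscle$muscle_mass / 1000, Lce0_m = Lce0,
       Lse0_m = Lse0, alpha_rad = a,
       Lmt_m = Lce0 * cos(a) + Lse0 * lse_rest,
       se_c = k$se[["c"]], se_k = k$se[["k"]], se_Lr = k$se[["Lr"]],
       pe1_c = k$pe1[["c"]], pe1_k = k$pe1[["k"]], pe1_Lr = k$pe1[["Lr"]],
       pe1_Lmax = k$pe1[["Lmax"]], pe1_eta = k$pe1[["eta"]],
       pe2_c = k$pe2[["c"]], pe2_k = k$pe2[["k"]], pe2_Lr = k$pe2[["Lr"]],
       fl_slow = unname(k$fl_slow), fl_fast = unname(k$fl_fast),
       fv_slow = unname(k$fv_slow), fv_fast = unname(k$fv_fast))
}

# Normalized tendon length from the constant-musculotendon-length constraint.
lse_from_lce <- function(Lce, mech) {
  (mech$Lmt_m - Lce * mech$Lce0_m * cos(mech$alpha_rad)) / mech$Lse0_m
}

#' Musculotendon state derivatives and one integration step
#'
#' `mt_derivs` evaluates the fascicle acceleration under the force balance
#' between the series-elastic element and the (contractile + parallel
#' passive) muscle forces, including the pennation kinematic term;
#' `mt_step` advances `(Lce, Vce)` by one RK4 step with `Fce` held constant.
#'
#' @param state list/vector with `Lce`, `Vce`
#' @param Fce contractile force (N)
#' @param mech constants from `mech_constants()`
#' @param dt step (s)
#' @return `mt_derivs`: list `dLce`, `dVce`; `mt_step`: updated state list
#'   with `Lce`, `Vce`, `Lse`, `Fse` (normalized), `Fout` (N)
#' @export
mt_derivs <- function(state, Fce, mech) {
  Lce <- state$Lce
  Vce <- state$Vce
  ca <- cos(mech$alpha_rad)
  Lse <- lse_from_lce(Lce, mech)
  Fse <- tendon_force(Lse)
  Fp1 <- passive_force_pe1(Lce, Vce)
  acc <- (mech$F0 * Fse * ca - (Fce + mech$F0 * Fp1) * ca^2) / mech$Mm_kg +
    (Vce * mech$Lce0_m)^2 * tan(mech$alpha_rad)^2 / (Lce * mech$Lce0_m)
  list(dLce = Vce, dVce = acc / mech$Lce0_m)
}

#' @rdname mt_derivs
#' @export
mt_step <- function(state, Fce, mech, dt) {
  k1 <- mt_derivs(state, Fce, mech)
  s2 <- list(Lce = state$Lce + dt / 2 * k1$dLce, Vce = state$Vce + dt / 2 * k1$dVce)
  k2 <- mt_derivs(s2, Fce, mech)
  s3 <- list(Lce = state$Lce + dt / 2 * k2$dLce, Vce = state$Vce + dt / 2 * k2$dVce)
  k3 <- mt_derivs(s3, Fce, mech)
  s4 <- list(Lce = state$Lce + dt * k3$dLce, Vce = state$Vce + dt * k3$dVce)
  k4 <- mt_derivs(s4, Fce, mech)
  Lce <- state$Lce + dt / 6 * (k1$dLce + 2 * k2$dLce + 2 * k3$dLce + k4$dLce)
  Vce <- state$Vce + dt / 6 * (k1$dVce + 2 * k2$dVce + 2 * k3$dVce + k4$dVce)
  if (!is.finite(Lce) || Lce <= 0)
    stop("musculotendon step became unstable (dt = ", dt, ")")
  Lse <- lse_from_lce(Lce, mech)
  Fse <- tendon_force(Lse)
  list(Lce = Lce, Vce = Vce, Lse = Lse, Fse = Fse, Fout = mech$F0 * Fse)
}

#' Passive equilibrium state
#'
#' Root-finds the fascicle length at which the passive muscle force balances
#' the tendon force at zero activation under the constant-musculotendon-length
#' constraint; every trial starts from this state.
#'
#' @param mech constants from `mech_constants()` (or a `muscle_config`)
#' @return state list with `Lce`, `Vce = 0`, `Lse`, `Fse`, `Fout`
#' @export
initial_equilibrium <- function(mech) {
  if (inherits(mech, "muscle_config")) mech <- mech_constants(mech)
  bal <- function(Lce) {
    ca <- cos(mech$alpha_rad)
    mech$F0 * tendon_force(lse_from_lce(Lce, mech)) * ca -
      mech$F0 * passive_force_pe1(Lce, 0) * ca^2
  }
  if (bal(0.5) * bal(1.5) > 0)
    stop("no passive equilibrium for Lce in (0.5, 1.5): check configuration")
  Lce <- uniroot(bal, c(0.5, 1.5), tol = 1e-12)$root
  Lse <- lse_from_lce(Lce, mech)
  Fse <- tendon_force(Lse)
  list(Lce = Lce, Vce = 0, Lse = Lse, Fse = Fse, Fout = mech$F0 * Fse)
}

#' Simulate one trial of the full model
#'
#' Generates stochastic spike trains from the synaptic-input trajectory,
#' integrates every unit's activation cascade and (optionally) the coupled
#' musculotendon mechanics, and returns tendon force and state traces. With
#' `use_see = FALSE` the fascicle is clamped at optimal length and the output
#' is the summed contractile force.
#'
#' @param pool a calibrated `mu_pool`
#' @param ueff synaptic-input trajectory sampled every `dt` (see
#'   [ramp_hold_input()])
#' @param dt integration step (s)
#' @param params a [rate_coding_params()]
#' @param use_see include the series-elastic element
#' @param keep_units unit indices whose force traces are returned
#' @param out_dt output sampling interval (s); traces are decimated to this
#' @param seed optional integer seed (set immediately before the run)
#' @return list of traces: `time`, `Fout` (N), `Fce`, `Lce`, `Vce`,
#'   `pool_spikes` (pool spike count per output sample), `unit_force`,
#'   `n_spikes`
#' @export
simulate_trial <- function(pool, ueff, dt = 5e-4,
                           params = rate_coding_params(), use_see = TRUE,
                           keep_units = integer(0), out_dt = 1e-3,
                           seed = NULL, mech_dt = 2.5e-5) {
  stopifnot(isTRUE(pool$calibrated))
  if (!is.null(seed)) set.seed(seed)
  mech <- mech_constants(pool$muscle, pool$F0)
  eq <- initial_equilibrium(mech)
  tab <- rate_coding_table(pool$units, params)
  cvm <- if (params$cv_mode == "input_dependent") 1L else 0L
  sy <- sag_yield_constants()
  out_every <- max(1L, as.integer(round(out_dt / dt)))
  mech_substeps <- max(1L, as.integer(ceiling(dt / mech_dt)))
  simulate_trial_cpp(ueff, dt, pool_par_matrix(pool), tab, pool$units$PT,
                     cvm, params$cv_constant, use_see, mech, eq$Lce,
                     as.integer(keep_units), out_every, sy$aS1, sy$aS2,
                     sy$TS, sy$cY, sy$VY, sy$TY, mech_substeps)
}

#' Ramp-and-hold synaptic input trajectory
#'
#' Zero phase, linear ramp, constant hold (the population-trial protocol).
#'
#' @param level hold level, fraction of maximal input
#' @param dt sampling interval (s)
#' @param zero_s,ramp_s,hold_s phase durations (s)
#' @return numeric vector sampled every `dt`
#' @export
ramp_hold_input <- function(level, dt = 5e-4, zero_s = 1, ramp_s = 2,
                            hold_s = 13) {
  t <- seq(0, zero_s + ramp_s + hold_s - dt / 2, by = dt)
  u <- ifelse(t < zero_s, 0,
              ifelse(t < zero_s + ramp_s, level * (t - zero_s) / ramp_s,
                     level))
  pmin(u, level)
}
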