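---
title: "Modelling motor noise in a motor unit pool: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling motor noise in a motor unit pool: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`munoise` simulates isometric force production by a pool of motor units of
the human tibialis anterior and asks how much force variability ("motor
noise") the motor unit force-generation machinery can produce on its own —
that is, from stochastic motoneuron discharge and unfused tetanic
contractions, without any fluctuation of the descending drive. This vignette
explains the model stages, the tunable parameters and their defaults, the
numerical choices, what the synthetic pool does and does not emulate, and the
design decisions that were genuinely open.

## Model overview

The simulation chain has three stages plus the musculotendon mechanics:

1. **Rate coding** — a common effective synaptic input $U_{\mathrm{eff}}(t)
   \in [0,1]$ drives all motoneurons. Each unit has a recruitment threshold
   $RT_i$; thresholds follow a geometric progression from $U_1 = 0.01$ to
   $U_r = 0.8$ and are assigned by the size principle. Above threshold, the
   discharge rate of a *high-threshold* unit ($RT_i > 0.1$) rises linearly
   from its minimal rate $MDR_i$ at recruitment to its peak rate $PDR_i$ at
   maximal input. *Low-threshold* units ($RT_i \le 0.1$) follow a continuous
   bilinear curve: a steep initial segment with relative slope
   $\lambda_i = -100\,RT_i + 21$, transitioning at the rate $1.1 f_{0.5,i}$
   to a shallow segment that reaches $PDR_i$ at maximal input. This
   reproduces the rapid acceleration and saturation of low-threshold human
   motor units. Spike trains are renewal processes: each interspike interval
   is $\mu (1 + cv\,Z/100)$ with $\mu$ the reciprocal of the current rate and
   $Z$ a standard normal truncated to $[-3.9, 3.9]$. The ISI variability
   $cv$ is either constant (0–20%) or input-dependent,
   $cv = 10 + 20\,e^{-(U_{\mathrm{eff}} - RT_i)\cdot 100 / 2.5}$ (the
   argument expressed in percent of maximal input, so the variability decays
   from 30% at recruitment toward 10%, matching the observed exponential
   decline with force level).

2. **Activation dynamics** — each spike releases calcium through a kernel
   $R(t) = \sum_j (1 - e^{-(t - t_j)/\tau_1})\, e^{-(t - t_j)/\tau_2}$. Free
   calcium $[c]$ and calcium bound to the myofilaments $[cf]$ follow a
   two-state kinetic system with release ($k_1$), reuptake ($k_2$), binding
   ($k_3$) and unbinding ($k_4$) rate constants, where
   $k_4 = k_{4i}(1 + \gamma A)$ couples unbinding to the current activation
   (cooperativity of cross-bridge formation, $\gamma = 0.8$ at optimal
   length). The bound fraction passes through a Hill nonlinearity
   $\tilde A = x^N / (x^N + K^N)$ with $x = [cf]\cdot S \cdot Y$, where $S$
   is the sag state of fast units and $Y$ the velocity-driven yield state of
   slow units; a first-order filter with time constant $\tau_3$ produces the
   activation $A \in [0,1]$. Four parameters ($k_3$, $N$, $K$, $\gamma$)
   scale affinely with fascicle length, $x = \phi\,x_0 (1 - L_{ce}) + x_0$.

3. **Musculotendon mechanics** — the contractile force is
   $F_{ce} = \sum_i PT_i\, A_i\, (FL_i \cdot FV_i + F_{pe2})$ with
   fiber-type-resolved force–length and force–velocity curves, and the
   fascicle works against a series-elastic element (tendon + aponeurosis)
   under a constant musculotendon length. The fascicle obeys a second-order
   equation of motion with the muscle mass and pennation kinematics; the
   tendon force is the model output. Because the tendon stretches as force
   rises, the fascicle shortens onto the ascending limb of the force–length
   curve — which is why the maximal tendon force is lower with the
   series-elastic element than without, and why the tendon acts as a
   mechanical low-pass filter on force fluctuations above a few Hz.

## The default pool

The default pool (`muscle_config()`, `build_pool()`) encodes the tibialis
anterior: 200 units; muscle mass 150 g; optimal fascicle length 6.8 cm;
optimal tendon length 27.5 cm; pennation 9.6°; density 1.06 g/cm³; specific
tension 31.8 N/cm². Maximal tetanic force is $F_0 = M\cos\alpha\,
\epsilon / (\rho L_{ce0}) \approx 652.5$ N. Peak tetanic forces follow the
exponential distribution $PT_i \propto e^{bi}$ with $b = \log(RP)/N$ and a
25-fold range, normalized so they sum to $F_0$; the smallest units are
labelled slow-twitch until their cumulative force reaches 40% of $F_0$,
which yields exactly 147 slow and 53 fast units. Contraction times are
deterministic Rayleigh quantiles rescaled to 20–85 ms; the slow units
receive the slowest times with no overlap between types, and times are
shuffled within type so size and speed are uncorrelated within a type.
Twitch–tetanus ratios span 0.07–0.53 with pool mean 0.23 and are constructed
to have exact within-type sample correlations with contraction time (0.638
slow, 0.704 fast) by adding orthogonalized seeded Gaussian jitter to the
standardized contraction times.

Two bounds in the source material disagree on the contraction-time range
(25–90 ms in one place, 20–85 ms in the figure describing the default pool);
the package defaults to 20–85 ms and exposes both bounds (`ct_min`,
`ct_max`). Note also that the discrete exponential form makes
$PT_N / PT_1 = RP^{(N-1)/N}$, a hair under the nominal fold-range; we keep
the printed formula.

## Per-unit calibration and f0.5

The twelve activation parameters of each unit are derived from one canonical
parameter set per fiber type (`seed_params()`; the fast seed is the slow
seed on a three-fold faster clock). These seeds are implementation constants
constructed so the canonical unit reproduces the activation-frequency
behavior the model targets: a sigmoidal, strictly monotone curve with mean
activation ≈ 50% of its plateau at $f_{0.5}$ (by definition), ≈ 16–21% at
$0.5 f_{0.5}$, ≈ 55–57% at $1.1 f_{0.5}$ and ≈ 85% at $2 f_{0.5}$; fusion of
about 70–75% at $1.1 f_{0.5}$, 50% fusion near $0.85 f_{0.5}$, and an
interspike interval at $f_{0.5}$ of about 1.1–1.2 contraction times.

`calibrate_unit()` then hits each unit's targets in three steps:

1. a seeded log-normal perturbation (10% CV) of $\{\alpha_S, k_2, k_3,
   k_{4i}, K, \tau_1\}$, which gives units individual activation-frequency
   shapes (and is what spreads the recruitment-pattern statistics below);
2. bisection on $k_1$ (calcium release gain) until the simulated
   twitch–tetanus ratio matches the unit's target — the ratio is monotone in
   $k_1$ because the tetanic plateau is Hill-saturated while the twitch is
   not;
3. one exact time rescaling (all rate constants $\times s$, all time
   constants $/s$) to match the target contraction time. Time dilation maps
   the trajectory onto itself in stretched time, so step 3 cannot disturb
   the ratio calibrated in step 2.

Because $\tau_2, \tau_3$ scale with contraction time, they decrease
monotonically from slow to fast units; $\gamma$ and $N$ are never varied
across units. $f_{0.5}$ is then determined empirically per unit: the plateau
is the mean activation (last 1 s of a 3-s train) at the lowest rate where a
further 20% rate increase changes it by less than 0.5%, and $f_{0.5}$ is
root-found as the rate giving half that plateau. $MDR = 0.5 f_{0.5}$ and
$PDR = 2 f_{0.5}$ close the loop between contraction speed and discharge
rates (the "speed match").

**A residual misfit, documented rather than hidden.** With the cooperativity
feedback as specified ($k_4$ increasing with $A$, $\gamma = 0.8$), the pool
mean activation at $0.5 f_{0.5}$ comes out near 21% rather than the nominal
16%: the positive feedback weakens unbinding at low activation, which
inflates low-rate summation relative to the plateau. The three anchors
"fusion ≈ 75% at $1.1 f_{0.5}$", "ISI at $f_{0.5}$ ≈ 1.18 contraction times"
and "≈ 16% at $0.5 f_{0.5}$" cannot be met simultaneously under this
feedback; weakening $\gamma$ recovers all three, and reversing the feedback
direction (unbinding decreasing with $A$) makes the activation-frequency
curve nearly step-like and is clearly wrong. We keep the specified form and
constants and accept the ~21% value. Tests assert the behavior the package
actually has.

**Sag and the twitch reference.** The sag state of fast units tracks
$a_{S1} = 20$ while the unit discharges below $0.1 f_{0.5}$ (or is silent)
and $a_{S2} = 0.96$ above, with time constant 15 ms. Taken literally, a 1-Hz
twitch train on a fast unit would keep $S = 20$ and the twitch would
saturate the Hill stage (twitch ≈ tetanus), which contradicts the pool's own
twitch–tetanus range. The package therefore computes all single-twitch
references (contraction time, twitch–tetanus ratio, fusion denominators)
with the sag state held at its sustained-discharge value $a_{S2}$, while
full simulations integrate the sag dynamics as written — there $a_{S1}$ only
shapes the first few tens of milliseconds after recruitment (a catch-like
transient), because discharging units always fire at or above
$0.5 f_{0.5} > 0.1 f_{0.5}$.

## Numerical choices

- **Single-unit integration**: fixed-step RK4 at `dt = 1e-4` s (0.1 ms) for
  calibration, activation-frequency and fusion curves. The release kernel is
  maintained through two exponential states (exactly equivalent to the
  per-spike sum, O(1) per step). Halving the step changes trajectories by
  well under 0.1% RMS (tested).
- **Population trials**: the per-unit states advance with RK4 at
  `dt = 5e-4` s, while the two-state musculotendon mechanics are sub-stepped
  at 25 µs with the activation-weighted force sums interpolated linearly
  within the step. The tendon is stiff (natural frequency near 90 Hz with
  the 150-g mass) and the force–velocity damping vanishes at low activation,
  so an un-split integrator rings at coarse steps; the split scheme matches
  a 5-µs-mechanics reference to four significant figures already at
  `dt = 1e-3`. Output traces are decimated to 1 kHz before statistics.
- **Degenerate inputs**: $[cf]$ is clipped to $[0,1]$ and free calcium to
  non-negative values after each step (the continuous system preserves both;
  clipping only absorbs roundoff). Length-scaled parameters are floored at
  $10^{-6}$ with a warning. ISIs are redrawn in the rare event
  $1 + cv\,Z/100 \le 0$ (possible only when $cv$ approaches 30% at
  recruitment). A trial aborts with an explicit instability error naming the
  step size if any state leaves its physical range.
- **Ties and boundaries**: the unit whose cumulative force crosses the
  40%-of-$F_0$ threshold is labelled slow; the first spike after a threshold
  crossing falls exactly at the crossing; de-recruitment cancels the pending
  spike without hysteresis.
- **Power spectra**: a single Hann-windowed periodogram of the full analysed
  segment (no segmentation, no overlap), with native bins averaged onto a
  0.5-Hz grid from 0 to 100 Hz and normalization chosen so the integrated
  density matches the signal variance. All spectral conclusions in the tests
  are relative (with vs without the series-elastic element), which is
  insensitive to the estimator flavor.
- **Musculotendon operating point**: the constant musculotendon length is
  fixed so the passive equilibrium sits exactly at optimal fascicle length;
  every trial starts from that equilibrium. The passive, tendon and
  force–length/velocity curve constants follow the classic feline-derived
  Hill-type parameterizations, collected in one constants file
  (`R/constants.R`).

## Protocols and statistics

Single-unit protocols use 3-s periodic trains on isolated units without the
series-elastic element; mean activation and the peak-to-peak ripple are
measured over the last second, and the degree of fusion is
$(1 - p/P_t)\cdot 100$ with $P_t$ the twitch amplitude. Population trials
are 16-s ramp-and-hold inputs (1 s zero, 2 s ramp, 13 s hold) at levels from
2.5% to 100% of maximal input; the last 10 s of the hold are analysed. SD
and CoV of force are reported raw and under two detrending recipes: ten 1-s
segments each linearly detrended, and the last 8 s split into two 4-s
segments each detrended with a 2nd-order polynomial; CoV always divides by
the raw mean. The reference models — the Fuglevand twitch-summation pool
(with its original 100-fold twitch range, 3-fold contraction-time range,
68-fold recruitment range, 8 Hz onset and 35→25 Hz peak rates, and the
sigmoidal rate-dependent gain) and the second-order noise filter
($\tau_1 = \tau_2 = 40$ ms, multiplicative input noise $\sigma_c = 0.5$,
10-ms steps) — run through the same protocol so their variability curves are
directly comparable, together with the empirical power law
$SD = c\cdot \mathrm{mean}^{1.05}$ anchored at 2.34% of maximum at 100%.

The sensitivity suite re-runs the population protocol with: no
series-elastic element; tetanic-force range 100; recruitment range 0.5; 100
units; the conventional onion-skin scheme (8 Hz onset for all units, peak
rates falling 35→25 Hz with size, with the handful of units whose new limits
make the bilinear form infeasible reverting to the linear scheme); and all
combined.

## What the synthetic pool does and does not emulate

The generator reproduces the *population structure* of the tibialis
anterior — size distribution, fiber-type split, speed distribution and
speed-matched discharge ranges — with deterministic, seed-reproducible
construction. It does not emulate: common fluctuations of synaptic drive
(inputs are noiseless by design; that is the point of the motor-noise
question), non-uniform synaptic weighting across the pool, motoneuron
intrinsic dynamics (persistent inward currents, adaptation, hysteresis),
fatigue or potentiation, pennation or musculotendon-length changes, or
correlated (synchronized) discharge between units. Passing tests therefore
show that the *force-generation machinery* behaves as specified; they do not
show that real force variability is this small — real muscles add drive
fluctuations on top, which is precisely the distinction the simulations are
built to make.

## Reduced problem sizes

The shipped test-suite and the acceptance script use desk-scale problem
sizes chosen as the package's own defaults: the full 200-unit pool for
calibration, the single-unit battery and all recruitment statistics; three
trials per level at six levels for the population properties. These sizes
give seed-stable statistics (the pool-level quantities move by well under a
tolerance across seeds) while keeping a complete run in minutes on one core;
`run_all()` exposes the full 12-level, 10-trial protocol.
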