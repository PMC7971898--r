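# Pool architecture: tetanic-force distribution, fiber types, contraction
# times, twitch-tetanus ratios, recruitment thresholds.

#' Maximal tetanic force of the muscle
#'
#' `F0 = M_m * cos(alpha) * epsilon / (rho * Lce0)` with the pennation angle
#' converted to radians: muscle mass (g) times specific tension (N/cm^2) over
#' density (g/cm^3) times optimal fascicle length (cm), projected along the
#' tendon line of action.
#'
#' @param muscle a [muscle_config()]
#' @return maximal tetanic force (N)
#' @export
compute_F0 <- function(muscle) {
  validate_muscle_config(muscle)
  with(muscle, muscle_mass * cos(pennation * pi / 180) * specific_tension /
         (density * Lce0))
}

#' Exponential distribution of peak tetanic forces
#'
#' `PT_i = F0 * exp(b*i) / sum_j exp(b*j)` with `b = log(RP)/N`, so the forces
#' sum to `F0` exactly and span (almost) an `RP`-fold range: the discrete
#' indexing gives `PT_N / PT_1 = RP^((N-1)/N)`.
#'
#' @param n number of units
#' @param rp fold-range of peak tetanic force
#' @param F0 maximal tetanic muscle force (N)
#' @return vector of peak tetanic forces, smallest first
#' @export
assign_tetanic_forces <- function(n, rp, F0) {
  if (n < 2) stop("need at least 2 units")
  if (rp <= 1) stop("rp must exceed 1")
  b <- log(rp) / n
  w <- exp(b * seq_len(n))
  F0 * w / sum(w)
}

#' Fiber-type split by cumulative force
#'
#' Units are labelled slow-twitch from the smallest up, until their cumulative
#' peak tetanic force first reaches `slow_force_fraction * F0`; the unit that
#' crosses the threshold is slow. The remainder are fast-twitch, so peak
#' tetanic forces of the two types never overlap.
#'
#' @param PT peak tetanic forces, ascending
#' @param slow_force_fraction fraction of total force from slow units
#' @return list with `n_slow` and factor `fiber_type`
#' @export
assign_fiber_types <- function(PT, slow_force_fraction) {
  if (slow_force_fraction <= 0 || slow_force_fraction >= 1)
    stop("slow_force_fraction must lie in (0,1)")
  cum <- cumsum(PT)
  n_slow <- which(cum >= slow_force_fraction * sum(PT))[1]
  ft <- factor(rep(c("slow", "fast"), c(n_slow, length(PT) - n_slow)),
               levels = c("slow", "fast"))
  list(n_slow = as.integer(n_slow), fiber_type = ft)
}

# Deterministic plotting-position quantiles of a (unit-scale) Rayleigh
# distribution, affinely rescaled to [lo, hi].
rayleigh_quantiles <- function(n, lo, hi) {
  q <- (seq_len(n) - 0.5) / n
  x <- sqrt(-2 * log(1 - q))
  lo + (hi - lo) * (x - x[1]) / (x[n] - x[1])
}

#' Contraction times from a Rayleigh-shaped distribution
#'
#' Draws `n` deterministic Rayleigh quantiles rescaled to `[ct_min, ct_max]`,
#' gives the slowest (largest) times to the slow-twitch units so the types do
#' not overlap, and shuffles times within each type (seeded) so contraction
#' time is uncorrelated with peak tetanic force within type.
#'
#' @param n_slow number of slow units (units `1..n_slow`)
#' @param n total number of units
#' @param ct_min,ct_max range of contraction times (ms)
#' @param seed integer seed for the within-type shuffle
#' @return contraction times (ms) in unit order
#' @export
assign_contraction_times <- function(n_slow, n, ct_min = 20, ct_max = 85,
                                     seed = 1L) {
  if (ct_min >= ct_max) stop("ct_min must be below ct_max")
  ct <- rayleigh_quantiles(n, ct_min, ct_max)
  slow_ct <- sort(ct[(n - n_slow + 1):n], decreasing = TRUE)
  fast_ct <- sort(ct[seq_len(n - n_slow)], decreasing = TRUE)
  out <- withr_seed(seed, {
    c(sample(slow_ct), sample(fast_ct))
  })
  out
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Construct a vector with an exact sample Pearson correlation r against x:
# standardized x plus the orthogonalized, standardized jitter.
exact_corr_vector <- function(x, r, jitter) {
  xs <- (x - mean(x)) / stats::sd(x)
  e <- jitter - mean(jitter)
  e <- e - xs * sum(e * xs) / sum(xs * xs)
  e <- e / stats::sd(e)
  r * xs + sqrt(1 - r^2) * e
}

#' Twitch-tetanus ratios correlated with contraction time
#'
#' Within each fiber type, builds a variate with the exact target sample
#' correlation against contraction time (standardized contraction time plus
#' orthogonalized seeded Gaussian jitter), maps it affinely onto
#' `[tt_min, tt_max]`, shifts the pool mean to `tt_mean` and clips.
#'
#' @param CT contraction times (ms), unit order
#' @param fiber_type factor of fiber types, unit order
#' @param tt_mean,tt_min,tt_max pool mean and range of the ratio
#' @param corr_slow,corr_fast target within-type correlation with contraction
#'   time; a jitter scale of zero is requested with `corr = 1`
#' @param seed integer seed for the jitter
#' @return twitch-tetanus ratios in unit order
#' @export
assign_twitch_tetanus_ratios <- function(CT, fiber_type, tt_mean = 0.23,
                                         tt_min = 0.07, tt_max = 0.53,
                                         corr_slow = 0.638, corr_fast = 0.704,
                                         seed = 1L) {
  if (!(tt_min < tt_mean && tt_mean < tt_max))
    stop("need tt_min < tt_mean < tt_max")
  if (abs(corr_slow) > 1 || abs(corr_fast) > 1)
    stop("infeasible correlation target (|r| > 1)")
  tt <- numeric(length(CT))
  withr_seed(seed, {
    for (ft in levels(fiber_type)) {
      idx <- which(fiber_type == ft)
      r <- if (ft == "slow") corr_slow else corr_fast
      if (length(idx) == 1) {
        tt[idx] <- (tt_min + tt_max) / 2
        next
      }
      # fewer than 3 units leaves no room for orthogonal jitter: rank map
      z <- if (abs(r) == 1 || length(idx) < 3) {
        sign(r) * scale(CT[idx])[, 1]
      } else {
        exact_corr_vector(CT[idx], r, rnorm(length(idx)))
      }
      tt[idx] <- tt_min + (tt_max - tt_min) * (z - min(z)) / (max(z) - min(z))
    }
  })
  tt <- tt + (tt_mean - mean(tt))
  pmin(pmax(tt, tt_min), tt_max)
}

#' Exponential distribution of recruitment thresholds
#'
#' `RT_i = U1 * exp((i-1) * log(Ur/U1) / (N-1))`: geometric interpolation from
#' the lowest threshold `U1` to the highest `Ur`, assigned in order of peak
#' tetanic force (size principle).
#'
#' @param n number of units
#' @param u1 threshold of the first (smallest) unit
#' @param ur threshold of the last (largest) unit
#' @return recruitment thresholds in unit order
#' @export
assign_recruitment_thresholds <- function(n, u1 = 0.01, ur = 0.8) {
  if (!(u1 > 0 && u1 < ur && ur <= 1)) stop("need 0 < u1 < ur <= 1")
  u1 * exp((seq_len(n) - 1) * log(ur / u1) / (n - 1))
}

#' Build a motor unit pool
#'
#' Constructs the default pool: exponential peak-tetanic-force distribution,
#' fiber-type split by cumulative force, Rayleigh-shaped contraction times
#' (shuffled within type), twitch-tetanus ratios correlated with contraction
#' time, and exponential recruitment thresholds. Activation-dynamics
#' parameters, `f0.5` and the discharge-rate limits are added by
#' [calibrate_pool()].
#'
#' @param muscle a [muscle_config()]
#' @param seed integer seed controlling the within-type shuffles and jitter
#' @param recruitment_scheme `"new_scheme"` (saturating low-threshold units)
#'   or `"onion_skin"`
#' @return an object of class `mu_pool`: list with `units` (data.frame),
#'   `muscle`, `F0`, `seed`, `recruitment_scheme`
#' @export
build_pool <- function(muscle = muscle_config(), seed = 1L,
                       recruitment_scheme = c("new_scheme", "onion_skin")) {
  recruitment_scheme <- match.arg(recruitment_scheme)
  F0 <- compute_F0(muscle)
  n <- muscle$n_units
  PT <- assign_tetanic_forces(n, muscle$rp, F0)
  ftyp <- assign_fiber_types(PT, muscle$slow_force_fraction)
  CT <- assign_contraction_times(ftyp$n_slow, n, muscle$ct_min, muscle$ct_max,
                                 seed = seed)
  tt <- assign_twitch_tetanus_ratios(CT, ftyp$fiber_type, muscle$tt_mean,
                                     muscle$tt_min, muscle$tt_max,
                                     muscle$tt_corr_slow,
                                     muscle$tt_corr_fast, seed = seed + 1L)
  RT <- assign_recruitment_thresholds(n, muscle$u1, muscle$ur)
  units <- data.frame(index = seq_len(n), fiber_type = ftyp$fiber_type,
                      PT = PT, CT_ms = CT, tt_ratio = tt, RT = RT,
                      f0_5 = NA_real_, MDR = NA_real_, PDR = NA_real_)
  pool <- list(units = units, muscle = muscle, F0 = F0, n_slow = ftyp$n_slow,
               seed = as.integer(seed), recruitment_scheme = recruitment_scheme,
               calibrated = FALSE)
  class(pool) <- "mu_pool"
  pool
}

#' @export
print.mu_pool <- function(x, ...) {
  cat(sprintf("Motor unit pool: %d units (%d slow, %d fast), F0 = %.1f N\n",
              nrow(x$units), x$n_slow, nrow(x$units) - x$n_slow, x$F0))
  cat(sprintf("  recruitment: %s, RT in [%.3g, %.3g], seed %d, %s\n",
              x$recruitment_scheme, min(x$units$RT), max(x$units$RT), x$seed,
              if (isTRUE(x$calibrated)) "calibrated" else "not calibrated"))
  invisible(x)
}

#' Write / read a pool as CSV
#'
#' Serializes the per-unit parameter table to a plain-text CSV (one row per
#' unit) with the pool-level configuration in `#`-prefixed header lines, and
#' reads it back.
#'
#' @param pool a `mu_pool`
#' @param path file path
#' @return `read_pool_csv` returns the reconstructed `mu_pool`
#' @export
write_pool_csv <- function(pool, path) {
  m <- pool$muscle
  hdr <- c(
    sprintf("# munoise pool: seed=%d scheme=%s calibrated=%d", pool$seed,
            pool$recruitment_scheme, as.integer(isTRUE(pool$calibrated))),
    sprintf("# muscle: %s", paste(sprintf("%s=%.10g", names(unclass(m)),
                                          unlist(unclass(m))), collapse = " "))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(pool$units, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pool_csv
#' @export
read_pool_csv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  units <- read.csv(text = lines[!startsWith(lines, "#")])
  units$fiber_type <- factor(units$fiber_type, levels = c("slow", "fast"))
  kv <- strsplit(sub("^# muscle: ", "", hdr[2]), " ")[[1]]
  vals <- lapply(strsplit(kv, "="), `[`, 2)
  names(vals) <- vapply(strsplit(kv, "="), `[`, "", 1)
  m <- do.call(muscle_config, lapply(vals, as.numeric))
  meta <- strsplit(sub("^# munoise pool: ", "", hdr[1]), " ")[[1]]
  getv <- function(key) sub(paste0(key, "="), "",
                            meta[startsWith(meta, paste0(key, "="))])
  pool <- list(units = units, muscle = m, F0 = compute_F0(m),
               n_slow = sum(units$fiber_type == "slow"),
               seed = as.integer(getv("seed")),
               recruitment_scheme = getv("scheme"),
               calibrated = getv("calibrated") == "1")
  class(pool) <- "mu_pool"
  pool
}
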