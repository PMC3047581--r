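# Synthetic amplification profiles with known ground truth — the package's
# test-data source. Trajectories follow the sigmoidal LRE model exactly (the
# closed form and the self-consistent per-cycle update agree to machine
# precision), so that per-cycle efficiency is exactly linear in cycle
# fluorescence and any deviation is attributable to an injected effect:
#   drift    - additive linear ramp on post-plateau cycles
#              (strength x fmax per cycle; 0.02 gives a plateau that keeps
#              climbing by 2% of F_max per cycle, a clearly visible drift)
#   collapse - efficiency deficit growing linearly after the half-maximum
#              cycle (strength per cycle, floor at zero efficiency: the
#              profile stalls below the model plateau)
#   arcing   - smooth sinusoidal modulation of E_max across the observable
#              lower rise (half period, peak fractional change = strength)
# Read noise is multiplicative (proportional to signal) with a small additive
# floor, reflecting instrument read precision that limits early cycles.

DISTORTION_STRENGTHS <- c(drift = 0.02, collapse = 0.08, arcing = 0.35)

with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate one amplification profile with known ground truth
#'
#' Builds the noiseless trajectory from the sigmoidal model with the supplied
#' kinetic parameters, starting from the initial fluorescence implied by the
#' true molecule count, amplicon size, strandedness and true OCF; optionally
#' injects one kinetic distortion; adds the background and seeded read noise.
#' Below `poisson_threshold` molecules the integer template count of the
#' reaction is drawn from a Poisson distribution (a zero draw yields a flat,
#' background-only profile), reproducing the stochastic template partitioning
#' that dominates limiting-dilution reactions.
#'
#' @param n_molecules True target molecules per reaction.
#' @param ocf True optical calibration factor, fluorescence units per ng
#'   dsDNA.
#' @param amplicon_size Amplicon length, bp.
#' @param strandedness `"double"` or `"single"`.
#' @param emax,fmax Sigmoidal model parameters: maximal efficiency and plateau
#'   fluorescence.
#' @param baseline Background fluorescence added to every cycle.
#' @param noise_sd Multiplicative read-noise SD (fraction of the reading);
#'   the 0.4% default reproduces run-level replicate F_0 CVs in the 25-30%
#'   range under default analysis settings, matching a well-behaved plate
#'   instrument.
#' @param noise_floor Additive read-noise SD, fluorescence units.
#' @param n_cycles Number of cycles.
#' @param distortion One of `"none"`, `"drift"`, `"collapse"`, `"arcing"`.
#' @param strength Distortion strength; defaults per mode to
#'   `c(drift = 0.02, collapse = 0.08, arcing = 0.35)`, severities comparable
#'   to published examples of each pathology.
#' @param poisson `TRUE`/`FALSE` to force or suppress the Poisson template
#'   draw; `NULL` (default) draws when `n_molecules < poisson_threshold`.
#' @param poisson_threshold Molecule count below which template counts are
#'   Poisson-distributed; default 10.
#' @param seed Seed for the profile's noise and template draw; required for
#'   reproducibility of any stochastic output.
#' @param profile_id,run_id,well,sample_name,amplicon_name Annotations.
#' @param is_calibration Mark the profile as a calibration profile.
#' @param known_ng Known DNA quantity (ng) for calibration profiles.
#' @param conv Mass-to-molecules constant; see [CONV_DS].
#' @return A list with `profile` (long-format tibble) and `truth` (one-row
#'   tibble retaining every generating parameter, the realized template count
#'   and the true F_0).
#' @examples
#' sim <- simulate_profile(n_molecules = 1000, seed = 1)
#' head(sim$profile)
#' sim$truth$f0
#' @export
simulate_profile <- function(n_molecules = 1e4,
                             ocf = 1e5,
                             amplicon_size = 150,
                             strandedness = "double",
                             emax = 0.95,
                             fmax = 4e6,
                             baseline = 5e4,
                             noise_sd = 0.004,
                             noise_floor = 10,
                             n_cycles = 50,
                             distortion = c("none", "drift", "collapse", "arcing"),
                             strength = NULL,
                             poisson = NULL,
                             poisson_threshold = 10,
                             seed = NULL,
                             profile_id = "sim_profile",
                             run_id = "sim_run",
                             well = "A1",
                             sample_name = "sample",
                             amplicon_name = "amplicon",
                             is_calibration = FALSE,
                             known_ng = NA_real_,
                             conv = CONV_DS) {
  distortion <- match.arg(distortion)
  stopifnot(
    n_molecules >= 0, ocf > 0, amplicon_size >= 1, emax > 0, fmax > 0,
    baseline >= 0, noise_sd >= 0, noise_floor >= 0, n_cycles >= 10
  )
  if (is.null(strength) && distortion != "none") {
    strength <- DISTORTION_STRENGTHS[[distortion]]
  }
  if ((noise_sd > 0 || noise_floor > 0 || isTRUE(poisson) ||
    (is.null(poisson) && n_molecules < poisson_threshold)) && is.null(seed)) {
    abort("A `seed` is required for stochastic output (noise or Poisson template draws).")
  }

  with_seed(seed, {
    draw_poisson <- isTRUE(poisson) ||
      (is.null(poisson) && n_molecules < poisson_threshold)
    realized <- if (draw_poisson) stats::rpois(1, n_molecules) else n_molecules

    strand_factor <- if (strandedness == "single") 2 else 1
    f0 <- realized * amplicon_size / (conv * strand_factor) * ocf
    cycles <- seq_len(n_cycles)

    if (realized > 0) {
      f <- predict_fc(f0, emax, fmax, cycles)
      f <- apply_distortion(f, f0, emax, fmax, distortion, strength)
    } else {
      f <- rep(0, n_cycles)
    }

    raw <- (baseline + f)
    if (noise_sd > 0) raw <- raw * (1 + stats::rnorm(n_cycles, 0, noise_sd))
    if (noise_floor > 0) raw <- raw + stats::rnorm(n_cycles, 0, noise_floor)

    profile <- tibble(
      profile_id = profile_id, run_id = run_id, well = well,
      sample_name = sample_name, amplicon_name = amplicon_name,
      amplicon_size = as.integer(amplicon_size), strandedness = strandedness,
      is_calibration = is_calibration, known_ng = known_ng,
      cycle = as.integer(cycles), fluorescence = raw
    )
    truth <- tibble(
      profile_id = profile_id, run_id = run_id,
      sample_name = sample_name, amplicon_name = amplicon_name,
      n_molecules = n_molecules, realized_molecules = realized,
      f0 = f0, emax = emax, fmax = fmax, ocf = ocf,
      amplicon_size = as.integer(amplicon_size), strandedness = strandedness,
      baseline = baseline, noise_sd = noise_sd,
      distortion = distortion, strength = strength %||% 0,
      seed = seed %||% NA_integer_
    )
    list(profile = profile, truth = truth)
  })
}

# Inject a kinetic distortion into a noiseless trajectory. Cycles before the
# rise midpoint are unchanged by drift; baseline cycles by all modes.
apply_distortion <- function(f, f0, emax, fmax, distortion, strength) {
  if (distortion == "none") {
    return(f)
  }
  n <- length(f)
  c_half <- c_half_from_fit(f0, emax, fmax)
  if (distortion == "drift") {
    cp <- which(f >= 0.95 * fmax)[1]
    if (!is.na(cp)) {
      k <- seq_len(n - cp + 1L)
      f[cp:n] <- f[cp:n] + strength * fmax * k
    }
    return(f)
  }
  if (distortion == "collapse") {
    cmid <- min(n, max(2L, ceiling(c_half)))
    for (cc in (cmid + 1L):n) {
      d <- strength * (cc - cmid)
      nxt <- f[cc - 1L] * (1 + emax - d) / (1 + emax * f[cc - 1L] / fmax)
      f[cc] <- max(nxt, f[cc - 1L]) # efficiency floored at zero: no signal loss
    }
    return(f)
  }
  # arcing: rebuild the trajectory with a smooth sinusoidal efficiency
  # excursion across the observable lower rise (half period over the six
  # cycles up to the half-maximum cycle, where fluorescence climbs from ~1%
  # to ~50% of the plateau). The LRE plot bows away from the line over that
  # fluorescence range and relaxes back to model behaviour above it -
  # distinguishing arcing from collapse and drift, whose deviations develop
  # above the half-maximum cycle and at the plateau respectively.
  lo <- c_half - 8
  len <- 6
  prev <- f0
  for (cc in seq_len(n)) {
    mod <- if (cc > lo && cc < lo + len) sin(pi * (cc - lo) / len) else 0
    e <- emax * (1 + strength * mod)
    f[cc] <- prev * (1 + e) / (1 + e * prev / fmax)
    prev <- f[cc]
  }
  f
}

#' Simulate a full run with calibration and ground truth
#'
#' Emulates a demonstration-style design: `n_amplicons` targets quantified in
#' `n_samples` samples with `n_replicates` technical PCR replicates each, plus
#' a set of optical-calibration profiles amplifying a known mass of lambda
#' gDNA under the same true OCF. Noise is independent per replicate; all
#' randomness derives from `seed`.
#'
#' @param seed Run seed (integer); per-profile seeds are derived from it.
#' @param n_amplicons,n_samples,n_replicates Design dimensions; default 3x3x3.
#' @param molecules Matrix (`n_amplicons` x `n_samples`) of true molecule
#'   counts per reaction; the default spans roughly 100 to 40,000 molecules,
#'   typical of reference-gene transcripts in a few ng of total RNA.
#' @param amplicon_sizes Amplicon lengths in bp, length `n_amplicons`.
#' @param strandedness Strandedness of the sample targets; `"single"` by
#'   default (first-strand cDNA).
#' @param ocf True optical calibration factor (fluorescence units / ng).
#' @param cal_ng Known lambda gDNA mass per calibration reaction, ng.
#' @param n_cal Number of calibration profiles.
#' @param cal_size Calibration amplicon length, bp (double-stranded).
#' @param distortion,strength Optional kinetic distortion applied to every
#'   sample profile (see [simulate_profile()]).
#' @param run_id Run identifier.
#' @inheritParams simulate_profile
#' @return A list with `profiles` (sample profiles, long format),
#'   `calibration` (calibration profiles, long format), `truth` (per-profile
#'   ground-truth table including the calibration profiles), and `ocf_true`.
#' @examples
#' run <- simulate_run(seed = 1)
#' dplyr::n_distinct(run$profiles$profile_id) # 27
#' @export
simulate_run <- function(seed,
                         n_amplicons = 3,
                         n_samples = 3,
                         n_replicates = 3,
                         molecules = NULL,
                         amplicon_sizes = NULL,
                         strandedness = "single",
                         ocf = 1e5,
                         cal_ng = 1e-5,
                         n_cal = 3,
                         cal_size = 200,
                         emax = 0.95,
                         fmax = 4e6,
                         baseline = 5e4,
                         noise_sd = 0.004,
                         noise_floor = 10,
                         n_cycles = 50,
                         distortion = "none",
                         strength = NULL,
                         run_id = "run1",
                         conv = CONV_DS) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (is.null(molecules)) {
    molecules <- round(outer(
      200 * 10^((seq_len(n_amplicons) - 1) %% 3),
      c(0.5, 1, 2)[((seq_len(n_samples) - 1) %% 3) + 1]
    ))
  }
  molecules <- matrix(molecules, n_amplicons, n_samples)
  if (is.null(amplicon_sizes)) {
    amplicon_sizes <- 120 + 30 * seq_len(n_amplicons)
  }
  stopifnot(length(amplicon_sizes) == n_amplicons)

  profile_seed <- function(k) as.integer((abs(seed) + 7919 * k) %% (.Machine$integer.max - 1) + 1)

  profiles <- list()
  truths <- list()
  k <- 0L
  for (i in seq_len(n_amplicons)) {
    for (j in seq_len(n_samples)) {
      for (r in seq_len(n_replicates)) {
        k <- k + 1L
        id <- sprintf("amp%d_S%d_r%d", i, j, r)
        sim <- simulate_profile(
          n_molecules = molecules[i, j], ocf = ocf,
          amplicon_size = amplicon_sizes[i], strandedness = strandedness,
          emax = emax, fmax = fmax, baseline = baseline,
          noise_sd = noise_sd, noise_floor = noise_floor, n_cycles = n_cycles,
          distortion = distortion, strength = strength,
          seed = profile_seed(k),
          profile_id = id, run_id = run_id,
          well = sprintf("%s%d", LETTERS[(k - 1) %% 8 + 1], (k - 1) %/% 8 + 1),
          sample_name = sprintf("S%d", j), amplicon_name = sprintf("amp%d", i),
          conv = conv
        )
        profiles[[k]] <- sim$profile
        truths[[k]] <- sim$truth
      }
    }
  }

  cal <- list()
  cal_truth <- list()
  cal_molecules <- cal_ng * conv / cal_size # double-stranded lambda equivalent
  for (r in seq_len(n_cal)) {
    k <- k + 1L
    sim <- simulate_profile(
      n_molecules = cal_molecules, ocf = ocf,
      amplicon_size = cal_size, strandedness = "double",
      emax = emax, fmax = fmax, baseline = baseline,
      noise_sd = noise_sd, noise_floor = noise_floor, n_cycles = n_cycles,
      seed = profile_seed(k),
      profile_id = sprintf("cal_r%d", r), run_id = run_id,
      well = sprintf("H%d", r),
      sample_name = "lambda_gDNA", amplicon_name = "lambda_cal",
      is_calibration = TRUE, known_ng = cal_ng, conv = conv
    )
    cal[[r]] <- sim$profile
    cal_truth[[r]] <- sim$truth
  }

  list(
    profiles = dplyr::bind_rows(profiles),
    calibration = dplyr::bind_rows(cal),
    truth = dplyr::bind_rows(c(truths, cal_truth)),
    ocf_true = ocf
  )
}
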