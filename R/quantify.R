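# From F_0 to molecules. The optical calibration factor (OCF, fluorescence
# units per ng of double-stranded DNA) converts the back-calculated initial
# fluorescence into target mass, and the amplicon size converts mass into a
# molecule count:
#   mass_ng   = F_0 / OCF
#   molecules = mass_ng * 9.1e11 / size_bp     (double-stranded)
#   molecules = mass_ng * 2 * 9.1e11 / size_bp (single-stranded targets)

#' Average technical replicates into one profile
#'
#' The average profile — the per-cycle arithmetic mean of the raw fluorescence
#' readings of a replicate set — is the primary working unit of the analysis:
#' averaging improves read precision markedly on some instruments. All
#' replicates must share the same cycle grid and annotations.
#'
#' @param replicates Long-format table of two or more replicate profiles with
#'   identical `cycle` grids, `sample_name`, `amplicon_name`, `amplicon_size`
#'   and `strandedness`.
#' @param profile_id Identifier for the new profile; default appends `"_avg"`
#'   to the replicate set's sample/amplicon names.
#' @return A single long-format profile whose `fluorescence` is the per-cycle
#'   mean, annotations inherited from the replicates.
#' @examples
#' reps <- tibble::tibble(
#'   profile_id = rep(c("a", "b"), each = 12), cycle = rep(1:12, 2),
#'   fluorescence = c(1:12 * 100, 1:12 * 300)
#' )
#' make_average_profile(reps)$fluorescence[1:2] # 200 600
#' @export
make_average_profile <- function(replicates, profile_id = NULL) {
  replicates <- as_tibble(replicates)
  ids <- unique(replicates$profile_id)
  if (length(ids) < 2L) {
    abort("An average profile requires at least 2 replicate profiles.")
  }
  grids <- split(replicates$cycle, replicates$profile_id)
  if (length(unique(vapply(grids, length, 1L))) != 1L ||
    !all(vapply(grids, function(g) identical(as.integer(g), as.integer(grids[[1]])), TRUE))) {
    abort("Replicates must share an identical cycle grid.")
  }
  for (col in intersect(
    c("sample_name", "amplicon_name", "amplicon_size", "strandedness", "is_calibration"),
    names(replicates)
  )) {
    if (length(unique(replicates[[col]])) > 1L) {
      abort(sprintf("Replicates disagree on '%s'; cannot average.", col))
    }
  }
  avg <- dplyr::summarise(
    dplyr::group_by(replicates, .data$cycle),
    fluorescence = mean(.data$fluorescence),
    .groups = "drop"
  )
  meta <- replicates[1, setdiff(names(replicates), c("cycle", "fluorescence", "profile_id", "well")), drop = FALSE]
  out <- dplyr::bind_cols(
    tibble(
      profile_id = profile_id %||% paste0(ids[1], "_avg"),
      cycle = as.integer(avg$cycle),
      fluorescence = avg$fluorescence
    ),
    meta[rep(1, nrow(avg)), , drop = FALSE]
  )
  dplyr::arrange(out, .data$cycle)
}

#' Compute the optical calibration factor
#'
#' Each analyzed calibration profile — amplification of a known mass of lambda
#' genomic DNA — yields `ocf_i = avg_f0_i / known_ng`; the reported OCF is
#' their mean (the "average optical calibration profile"), with the standard
#' deviation as dispersion. Flagged calibration profiles are excluded.
#'
#' @param analyzed_cal Result of [analyze_profiles()] on calibration profiles.
#' @param known_ng Known quantity of double-stranded DNA per calibration
#'   reaction, in ng. Defaults to the profiles' `known_ng` column.
#' @return An object of class `lre_ocf`: list with `value` (fluorescence units
#'   per ng dsDNA), `sd`, `n`, `per_profile` (tibble), `known_ng`.
#' @export
compute_ocf <- function(analyzed_cal, known_ng = NULL) {
  analyzed_cal <- as_tibble(analyzed_cal)
  if (is.null(known_ng)) {
    if (!"known_ng" %in% names(analyzed_cal)) {
      abort("Supply `known_ng` or include a known_ng column in the calibration profiles.")
    }
    known_ng <- analyzed_cal$known_ng
  }
  if (any(!is.finite(known_ng) | known_ng <= 0)) {
    abort("`known_ng` must be positive and finite.")
  }
  ok <- is.na(analyzed_cal$flag) & is.finite(analyzed_cal$avg_f0)
  if (!any(ok)) {
    abort("No calibration profile has a valid LRE fit; cannot compute an OCF.")
  }
  per <- tibble(
    profile_id = analyzed_cal$profile_id[ok],
    avg_f0 = analyzed_cal$avg_f0[ok],
    known_ng = rep_len(known_ng, nrow(analyzed_cal))[ok]
  )
  per$ocf <- per$avg_f0 / per$known_ng
  structure(
    list(
      value = mean(per$ocf),
      sd = if (nrow(per) >= 2) stats::sd(per$ocf) else NA_real_,
      n = nrow(per),
      per_profile = per,
      known_ng = unique(per$known_ng)
    ),
    class = "lre_ocf"
  )
}

#' @export
print.lre_ocf <- function(x, ...) {
  cat(sprintf(
    "<lre_ocf> %.6g fluorescence units / ng dsDNA (sd %.3g, n = %d)\n",
    x$value, x$sd, x$n
  ))
  invisible(x)
}

#' Convert initial fluorescence to molecules per reaction
#'
#' `mass_ng = f0 / ocf`, then `molecules = mass_ng * conv / amplicon_size`
#' with `conv = 9.1e11` bp x molecules / ng for double-stranded targets
#' (Avogadro's number over 660 g/mol per base pair); single-stranded targets
#' (e.g. first-strand cDNA) carry twice as many molecules per ng (330 g/mol
#' per base).
#'
#' @param f0 Initial target fluorescence (fluorescence units), > 0.
#' @param ocf An [compute_ocf()] result, or a bare numeric OCF value.
#' @param amplicon_size Amplicon length in bp, >= 1.
#' @param strandedness `"double"` or `"single"`.
#' @param conv Conversion constant for double-stranded DNA; see [CONV_DS].
#' @return Molecules per reaction (numeric, vectorized over `f0`).
#' @examples
#' molecules_from_f0(1e4, ocf = 1e4, amplicon_size = 100, strandedness = "double")
#' @export
molecules_from_f0 <- function(f0, ocf, amplicon_size, strandedness = "double",
                              conv = CONV_DS) {
  ocf_value <- if (inherits(ocf, "lre_ocf")) ocf$value else ocf
  stopifnot(is.numeric(ocf_value), all(ocf_value > 0), all(amplicon_size >= 1))
  strand_factor <- ifelse(strandedness == "single", 2, 1)
  (f0 / ocf_value) * conv * strand_factor / amplicon_size
}

#' Quantify replicate sets of an analyzed run
#'
#' Groups profiles into replicate sets by (`run_id`, `sample_name`,
#' `amplicon_name`), analyzes each set's average profile, and converts its
#' average F_0 into molecules per reaction. When the quantity falls below
#' `params$low_copy_threshold` (10 molecules by default) — judged on either
#' the average-profile quantity or the mean per-replicate quantity — template
#' partitioning among replicates follows a Poisson distribution: replicates
#' carry genuinely different integer template counts, their averaged profile
#' is a smear of time-shifted curves whose quantity is biased high, and the
#' set quantity becomes the mean of the per-replicate quantities instead
#' (replicates flagged non-amplifying count as 0 molecules in that mean — an
#' expected outcome at limiting dilution). Such sets are flagged as
#' Poisson-regime; the path taken is always recorded.
#'
#' Also computes each set's replicate F_0 CV and warns when replicate C_1/2
#' values span more than `params$c_half_warn_range` cycles (replicates not
#' tightly clustered).
#'
#' @param profiles Long-format table of sample profiles (not calibration).
#' @param ocf An [compute_ocf()] result or bare numeric OCF.
#' @param params An [lre_params()] object.
#' @param analyzed Optional precomputed [analyze_profiles()] result for
#'   `profiles` (avoids re-analysis).
#' @return One row per replicate set: `run_id`, `sample_name`,
#'   `amplicon_name`, `amplicon_size`, `strandedness`, `n_replicates`,
#'   `n_valid`, `avg_profile_molecules`, `molecules`, `path`
#'   (`"average_profile"` or `"replicate_mean"`), `f0_cv`, `c_half`,
#'   `c_half_range`, `flag`, plus list-columns `replicates` (per-replicate
#'   quantities) and `avg_analysis` (the average profile's analysis row).
#' @examples
#' run <- simulate_run(seed = 7)
#' cal <- analyze_profiles(run$calibration)
#' ocf <- compute_ocf(cal)
#' quantify_replicates(run$profiles, ocf)
#' @export
quantify_replicates <- function(profiles, ocf, params = lre_params(), analyzed = NULL) {
  profiles <- validate_profiles(profiles)
  need <- c("run_id", "sample_name", "amplicon_name", "amplicon_size", "strandedness")
  if (!all(need %in% names(profiles))) {
    abort(paste0(
      "Quantification needs profile annotations: ",
      paste(setdiff(need, names(profiles)), collapse = ", ")
    ))
  }
  if (is.null(analyzed)) analyzed <- analyze_profiles(profiles, params)

  key <- interaction(profiles$run_id, profiles$sample_name, profiles$amplicon_name,
    drop = TRUE, lex.order = TRUE
  )
  sets <- split(profiles, key)
  rows <- lapply(sets, function(set) {
    quantify_one_set(set, analyzed, ocf, params)
  })
  dplyr::bind_rows(rows)
}

quantify_one_set <- function(set, analyzed, ocf, params) {
  ids <- unique(set$profile_id)
  reps <- analyzed[analyzed$profile_id %in% ids, , drop = FALSE]
  meta <- set[1, c("run_id", "sample_name", "amplicon_name", "amplicon_size", "strandedness"), drop = FALSE]

  valid <- is.na(reps$flag) & is.finite(reps$avg_f0)
  rep_molecules <- rep(NA_real_, nrow(reps))
  rep_molecules[valid] <- molecules_from_f0(
    reps$avg_f0[valid], ocf, meta$amplicon_size, meta$strandedness,
    conv = params$conv
  )
  # non-amplifying replicates are genuine zero-template reactions in the
  # Poisson regime
  rep_molecules[!valid & reps$flag %in% c("non_amplifying", "no_start_cycle")] <- 0
  rep_tbl <- tibble(
    profile_id = reps$profile_id, avg_f0 = reps$avg_f0,
    molecules = rep_molecules, flag = reps$flag
  )

  f0_cv <- if (sum(valid) >= 2) {
    stats::sd(reps$avg_f0[valid]) / mean(reps$avg_f0[valid])
  } else {
    NA_real_
  }
  c_half_range <- if (sum(valid) >= 2) diff(range(reps$c_half[valid])) else NA_real_
  if (is.finite(c_half_range) && c_half_range > params$c_half_warn_range) {
    warn(sprintf(
      "Replicate set %s/%s/%s: C_1/2 range %.2f cycles exceeds %.2f - replicates are not tightly clustered.",
      meta$run_id, meta$sample_name, meta$amplicon_name, c_half_range, params$c_half_warn_range
    ))
  }

  avg_analysis <- NULL
  avg_molecules <- NA_real_
  avg_c_half <- NA_real_
  flag <- NA_character_
  if (length(ids) >= 2L) {
    avg_prof <- make_average_profile(set, profile_id = paste(
      meta$sample_name, meta$amplicon_name, "avg",
      sep = "_"
    ))
    avg_analysis <- analyze_profiles(avg_prof, params)
    if (is.na(avg_analysis$flag) && is.finite(avg_analysis$avg_f0)) {
      avg_molecules <- molecules_from_f0(
        avg_analysis$avg_f0, ocf, meta$amplicon_size, meta$strandedness,
        conv = params$conv
      )
      avg_c_half <- avg_analysis$c_half
    }
  } else if (sum(valid) == 1L) {
    avg_molecules <- rep_tbl$molecules[valid]
    avg_c_half <- reps$c_half[valid]
  }

  usable <- is.finite(rep_tbl$molecules)
  rep_mean <- if (any(usable)) mean(rep_tbl$molecules[usable]) else NA_real_
  rep_median <- if (any(usable)) stats::median(rep_tbl$molecules[usable]) else NA_real_
  # Poisson regime: below ~10 molecules the template count differs between
  # replicates, the averaged profile is a smear of time-shifted curves rather
  # than a single amplification curve, and its quantity is biased high — so
  # the per-replicate quantities must also be consulted for the regime
  # decision, and the median guards it against a single outlier estimate.
  thr <- params$low_copy_threshold
  low_copy <- (is.finite(avg_molecules) && avg_molecules < thr) ||
    (is.finite(rep_mean) && rep_mean < thr) ||
    (is.finite(rep_median) && rep_median < thr)
  if (low_copy && is.finite(rep_mean)) {
    molecules <- rep_mean
    path <- "replicate_mean"
    flag <- "poisson_regime"
  } else if (is.finite(avg_molecules)) {
    molecules <- avg_molecules
    path <- "average_profile"
  } else if (any(is.finite(rep_tbl$molecules))) {
    # average profile unusable; fall back to replicate mean, flagged
    molecules <- mean(rep_tbl$molecules[is.finite(rep_tbl$molecules)])
    path <- "replicate_mean"
    flag <- "average_profile_flagged"
  } else {
    molecules <- NA_real_
    path <- NA_character_
    flag <- "no_valid_profile"
  }

  out <- meta
  out$n_replicates <- length(ids)
  out$n_valid <- sum(valid)
  out$avg_profile_molecules <- avg_molecules
  out$molecules <- molecules
  out$path <- path
  out$f0_cv <- f0_cv
  out$c_half <- avg_c_half
  out$c_half_range <- c_half_range
  out$flag <- flag
  out$replicates <- list(rep_tbl)
  out$avg_analysis <- list(avg_analysis)
  out
}

#' Replicate F_0 coefficient of variation
#'
#' Sample standard deviation over mean of the per-replicate average F_0
#' values of one replicate set — the set-level precision statistic.
#'
#' @param f0 Numeric vector of per-replicate average F_0 values (valid fits
#'   only).
#' @return The CV as a fraction; `NA` with fewer than 2 values.
#' @examples
#' replicate_f0_cv(c(90, 110)) # 0.1414
#' @export
replicate_f0_cv <- function(f0) {
  f0 <- f0[is.finite(f0)]
  if (length(f0) < 2L) {
    return(NA_real_)
  }
  stats::sd(f0) / mean(f0)
}

#' Run-level average replicate F_0 CV
#'
#' The mean, over all replicate sets with a defined CV (two or more valid
#' replicates), of the set-level replicate F_0 CVs — the "Av Repl-F_0 CV"
#' intra-run precision statistic used to judge window-selection settings and
#' overall assay performance.
#'
#' @param set_cvs Numeric vector of set-level CVs (from [replicate_f0_cv()] or
#'   the `f0_cv` column of [quantify_replicates()]).
#' @return The run-level mean CV as a fraction; `NA` when no set has a defined
#'   CV.
#' @examples
#' average_replicate_f0_cv(c(0.10, 0.20)) # 0.15
#' @export
average_replicate_f0_cv <- function(set_cvs) {
  set_cvs <- set_cvs[is.finite(set_cvs)]
  if (!length(set_cvs)) {
    return(NA_real_)
  }
  mean(set_cvs)
}
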