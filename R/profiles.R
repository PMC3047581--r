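# Fluorescence profiles are kept in long/tidy form: one row per (profile,
# cycle), annotation columns repeated down the profile. Required columns:
#   profile_id, cycle, fluorescence
# and for quantification additionally:
#   run_id, sample_name, amplicon_name, amplicon_size, strandedness,
#   is_calibration (+ known_ng for calibration profiles).

PROFILE_META_COLS <- c(
  "run_id", "well", "sample_name", "amplicon_name",
  "amplicon_size", "strandedness", "is_calibration", "known_ng"
)

#' Validate a table of fluorescence profiles
#'
#' Checks the long-format invariants: `profile_id`, `cycle`, `fluorescence`
#' columns present; within each profile the cycles start at 1 and are
#' consecutive with at least 10 readings, all finite; `amplicon_size` (if
#' present) is a positive integer and `strandedness` is `"double"` or
#' `"single"`; annotation columns are constant within a profile.
#'
#' @param profiles A data frame of per-cycle fluorescence readings.
#' @return The input as a tibble, invisibly validated (errors describe the
#'   offending profile).
#' @export
validate_profiles <- function(profiles) {
  profiles <- as_tibble(profiles)
  need <- c("profile_id", "cycle", "fluorescence")
  missing <- setdiff(need, names(profiles))
  if (length(missing)) {
    abort(paste0("Missing profile column(s): ", paste(missing, collapse = ", ")))
  }
  split_idx <- split(seq_len(nrow(profiles)), profiles$profile_id)
  for (id in names(split_idx)) {
    rows <- split_idx[[id]]
    cyc <- profiles$cycle[rows]
    fl <- profiles$fluorescence[rows]
    if (length(cyc) < 10L) {
      abort(sprintf("Profile '%s': fewer than 10 cycles (%d).", id, length(cyc)))
    }
    if (cyc[1] != 1L || any(diff(cyc) != 1L)) {
      abort(sprintf("Profile '%s': cycles must start at 1 and be consecutive.", id))
    }
    if (any(!is.finite(fl))) {
      abort(sprintf("Profile '%s': non-finite fluorescence reading(s).", id))
    }
    for (col in intersect(PROFILE_META_COLS, names(profiles))) {
      if (length(unique(profiles[[col]][rows])) > 1L) {
        abort(sprintf("Profile '%s': annotation column '%s' is not constant.", id, col))
      }
    }
    if ("amplicon_size" %in% names(profiles)) {
      sz <- profiles$amplicon_size[rows][1]
      if (!is.finite(sz) || sz < 1) {
        abort(sprintf("Profile '%s': amplicon_size must be >= 1 bp.", id))
      }
    }
    if ("strandedness" %in% names(profiles)) {
      st <- profiles$strandedness[rows][1]
      if (!st %in% c("double", "single")) {
        abort(sprintf("Profile '%s': strandedness must be 'double' or 'single'.", id))
      }
    }
  }
  profiles
}

#' Subtract the fluorescence background and compute per-cycle efficiencies
#'
#' Estimates each profile's background as the mean raw reading over
#' `baseline_cycles` (or uses the fixed `baseline` if supplied), subtracts it,
#' and computes the per-cycle efficiency `ec = fc/fc_prev - 1` for every cycle
#' whose predecessor has positive background-subtracted fluorescence.
#'
#' A baseline range that overlaps the amplification rise (any reading in the
#' range above 10% of the profile's dynamic range) corrupts the background
#' estimate; such profiles are rejected with a diagnostic, or flagged in the
#' `baseline_flag` column when `action = "flag"`.
#'
#' @param profiles Long-format profile table (see [validate_profiles()]); may
#'   already contain several profiles.
#' @param baseline_cycles Inclusive cycle range used for background
#'   estimation; default 4-9.
#' @param baseline Optional fixed background level overriding estimation (0
#'   for pre-baselined data).
#' @param action `"error"` (default) to reject profiles whose baseline range
#'   overlaps the rise, `"flag"` to record the problem in `baseline_flag` and
#'   keep going.
#' @return The input tibble with added columns `baseline`, `fc`
#'   (background-subtracted fluorescence), `ec` (per-cycle efficiency, `NA`
#'   where undefined) and, when `action = "flag"`, `baseline_flag`.
#' @examples
#' prof <- tibble::tibble(
#'   profile_id = "p1", cycle = 1:12,
#'   fluorescence = c(rep(100, 9), 200, 400, 800)
#' )
#' subtract_baseline(prof, baseline_cycles = 1:4)
#' @export
subtract_baseline <- function(profiles, baseline_cycles = 4:9, baseline = NULL,
                              action = c("error", "flag")) {
  action <- match.arg(action)
  profiles <- as_tibble(profiles)
  stopifnot(all(c("profile_id", "cycle", "fluorescence") %in% names(profiles)))

  one <- function(df) {
    raw <- df$fluorescence
    flag <- NA_character_
    if (is.null(baseline)) {
      in_range <- df$cycle %in% baseline_cycles
      if (!any(in_range)) {
        abort("`baseline_cycles` do not intersect the profile's cycles.")
      }
      b <- mean(raw[in_range])
      # guard: baseline range must precede the rise (when a rise exists at all)
      rng <- max(raw) - min(raw)
      rise_present <- rng > 0.5 * max(abs(raw))
      if (rise_present && max(raw[in_range]) - min(raw) > 0.10 * rng) {
        flag <- sprintf(
          "baseline cycles %d-%d overlap the amplification rise",
          min(baseline_cycles), max(baseline_cycles)
        )
        if (action == "error") {
          abort(sprintf("Profile '%s': %s.", df$profile_id[1], flag))
        }
      }
    } else {
      b <- baseline
    }
    fc <- raw - b
    ec <- cycle_efficiency(dplyr::lag(fc), fc)
    df$baseline <- b
    df$fc <- fc
    df$ec <- ec
    if (action == "flag") df$baseline_flag <- flag
    df
  }
  ids <- factor(profiles$profile_id, levels = unique(profiles$profile_id))
  dplyr::bind_rows(lapply(split(profiles, ids), one))
}

#' Fit-free half-maximum cycle of an observed profile
#'
#' A provisional estimate of the cycle at which fluorescence reaches half of
#' the plateau, computed without any model fit: the plateau is the mean of the
#' cycles within 5% of the maximum (at least two such cycles are required),
#' and the crossing of half that level is located by linear interpolation
#' between the last cycle below and the first cycle at or above it. Used to
#' seed the default start-cycle rule, which cannot depend on a window fit that
#' does not yet exist.
#'
#' @param profile A single baselined profile (columns `cycle`, `fc`).
#' @return The fractional crossing cycle, or `NA` for a profile that never
#'   reaches half of its plateau (non-amplifying).
#' @export
observed_half_max_cycle <- function(profile) {
  fc <- profile$fc
  cyc <- profile$cycle
  mx <- suppressWarnings(max(fc))
  if (!is.finite(mx) || mx <= 0) {
    return(NA_real_)
  }
  plateau_idx <- which(fc >= 0.95 * mx)
  if (length(plateau_idx) < 2L) {
    return(NA_real_)
  }
  plateau <- mean(fc[plateau_idx])
  half <- plateau / 2
  i <- which(fc >= half)[1]
  if (is.na(i)) {
    return(NA_real_)
  }
  if (i == 1L) {
    return(as.numeric(cyc[1]))
  }
  cyc[i - 1] + (half - fc[i - 1]) / (fc[i] - fc[i - 1])
}

# Does the profile show genuine amplification? Scale-equivariant: signal must
# exceed 10x the read-noise level estimated from the baseline cycles.
profile_amplifies <- function(profile, baseline_cycles) {
  fc <- profile$fc
  noise <- stats::sd(profile$fluorescence[profile$cycle %in% baseline_cycles])
  if (!is.finite(noise)) noise <- 0
  mx <- suppressWarnings(max(fc))
  is.finite(mx) && mx > 10 * noise && mx > 0
}
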