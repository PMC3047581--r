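# Automated LRE window selection: pick the start cycle (bottom of the window),
# then expand the window upward, one cycle at a time, while the F_0 value of
# the cycle just above the window agrees with the window-average F_0 to within
# the F_0 threshold. The fit and window average are recomputed after every
# expansion (fully recursive).

#' Default start-cycle rule: first cycle below the half-maximum cycle
#'
#' The largest integer cycle strictly below the fit-free half-maximum cycle of
#' the profile (see [observed_half_max_cycle()]); an exact integer crossing
#' steps down one further, and the result never goes below cycle 2 (where the
#' first efficiency is defined).
#'
#' @param profile A single baselined profile (columns `cycle`, `fc`).
#' @return Integer start cycle, or `NA` for a non-amplifying profile.
#' @export
select_start_cycle_default <- function(profile) {
  h <- observed_half_max_cycle(profile)
  if (is.na(h)) {
    return(NA_integer_)
  }
  s <- floor(h)
  if (s == h) s <- s - 1
  as.integer(max(2, s))
}

#' Minimum-F_C start-cycle rule
#'
#' With a manually specified minimum fluorescence, the start cycle is the
#' cycle *following* the first cycle whose baseline-subtracted reading exceeds
#' the minimum: that earlier cycle supplies the efficiency denominator of the
#' start cycle. Lowering the minimum moves the window down into cycles with
#' poorer optical read precision; see [optimize_min_fc()].
#'
#' @param profile A single baselined profile (columns `cycle`, `fc`).
#' @param min_fc Minimum fluorescence, same units as the readings.
#' @return Integer start cycle, or `NA` when no cycle exceeds `min_fc` or the
#'   first to exceed it is the final cycle.
#' @export
select_start_cycle_min_fc <- function(profile, min_fc) {
  stopifnot(is.numeric(min_fc), length(min_fc) == 1L)
  i <- which(profile$fc > min_fc)[1]
  if (is.na(i) || i >= nrow(profile)) {
    return(NA_integer_)
  }
  as.integer(profile$cycle[i] + 1L)
}

#' Expand the LRE window upward under the F_0 threshold
#'
#' Starting from a window of `initial_window_size` cycles at `start_cycle`,
#' repeatedly: fit the LRE regression on the current window; back-calculate
#' the F_0 of the cycle immediately above the window using the current fit;
#' if its fractional difference from the window-average F_0 is within
#' `f0_threshold`, grow the window by that cycle and refit; otherwise stop.
#' Expansion also stops at the end of the profile, or when the candidate
#' cycle's fluorescence reaches 99.9% of the fitted plateau (the F_0
#' back-calculation has a pole at `fmax`).
#'
#' @param profile A single baselined profile (columns `cycle`, `fc`, `ec`).
#' @param start_cycle First cycle of the window.
#' @param params An [lre_params()] object (uses `initial_window_size` and
#'   `f0_threshold`).
#' @return A list with elements `window` ([lre_window()]), `fit` ([fit_lre()]
#'   result), `trace` (tibble of candidate cycles: `cycle`, `fc`, `ec`, `f0`,
#'   `pct_diff`, `included`), `stop_reason`, and `flag` (`NA` or a reason the
#'   profile could not be windowed).
#' @examples
#' prof <- subtract_baseline(simulate_profile(seed = 1, noise_sd = 0)$profile)
#' expand_window(prof, select_start_cycle_default(prof), lre_params())
#' @export
expand_window <- function(profile, start_cycle, params = lre_params()) {
  stopifnot(inherits(params, "lre_params"))
  empty_trace <- tibble(
    cycle = integer(), fc = double(), ec = double(),
    f0 = double(), pct_diff = double(), included = logical()
  )
  fail <- function(flag, stop_reason = flag) {
    list(
      window = NULL, fit = NULL, trace = empty_trace,
      stop_reason = stop_reason, flag = flag
    )
  }
  n <- max(profile$cycle)
  if (is.na(start_cycle)) {
    return(fail("no_start_cycle"))
  }
  start_cycle <- max(2L, as.integer(start_cycle))
  ws <- params$initial_window_size
  if (start_cycle + ws - 1L > n) {
    return(fail("window_truncated"))
  }

  win <- lre_window(start_cycle, ws)
  fit <- fit_lre(profile, win)
  if (!fit$valid) {
    return(fail("aberrant_initial_fit"))
  }

  trace <- list()
  stop_reason <- NA_character_
  repeat {
    cand <- win$start_cycle + win$size
    if (cand > n) {
      stop_reason <- "end_of_profile"
      break
    }
    i <- match(cand, profile$cycle)
    fc_c <- profile$fc[i]
    ec_c <- profile$ec[i]
    if (!is.finite(fc_c) || fc_c <= 0 || fc_c >= 0.999 * fit$fmax) {
      trace[[length(trace) + 1L]] <- tibble(
        cycle = cand, fc = fc_c, ec = ec_c,
        f0 = NA_real_, pct_diff = NA_real_, included = FALSE
      )
      stop_reason <- "fmax_pole"
      break
    }
    f0_c <- back_calculate_f0(fc_c, cand, fit$emax, fit$fmax)
    pct <- abs(f0_c - fit$avg_f0) / fit$avg_f0
    ok <- is.finite(pct) && pct <= params$f0_threshold
    trace[[length(trace) + 1L]] <- tibble(
      cycle = cand, fc = fc_c, ec = ec_c,
      f0 = f0_c, pct_diff = pct, included = ok
    )
    if (!ok) {
      stop_reason <- "f0_threshold"
      break
    }
    grown <- lre_window(win$start_cycle, win$size + 1L)
    new_fit <- fit_lre(profile, grown)
    if (!new_fit$valid) {
      trace[[length(trace)]]$included <- FALSE
      stop_reason <- "fit_invalid_on_expansion"
      break
    }
    win <- grown
    fit <- new_fit
  }
  list(
    window = win, fit = fit,
    trace = dplyr::bind_rows(empty_trace, !!!trace),
    stop_reason = stop_reason, flag = NA_character_
  )
}

#' Analyze fluorescence profiles end to end
#'
#' For each profile: subtract the background, choose the start cycle (the
#' minimum-F_C rule when `params$min_fc` is set, the half-maximum rule
#' otherwise), expand the LRE window under the F_0 threshold, and classify the
#' amplification kinetics. Deterministic for fixed input and parameters.
#' Profiles that cannot be analyzed (no amplification, baseline overlap,
#' aberrant initial fit, truncated window) carry a `flag` and `NA` results
#' instead of numbers — a flagged profile is never silently quantified.
#'
#' @param profiles Long-format profile table (see [validate_profiles()]).
#' @param params An [lre_params()] object.
#' @return One row per profile: annotation columns, `baseline`, `flag`,
#'   `start_cycle`, `window_start`, `window_size`, `emax`, `delta_e`, `fmax`,
#'   `r2`, `avg_f0`, `c_half`, `stop_reason`, `classification`, `drift_score`,
#'   `arc_score`, plus list-columns `fit` (the [fit_lre()] objects), `trace`
#'   (window-expansion traces) and `data` (the baselined per-cycle tibbles).
#' @examples
#' run <- simulate_run(seed = 1)
#' res <- analyze_profiles(run$profiles)
#' dplyr::select(res, profile_id, emax, avg_f0, c_half, classification)
#' @export
analyze_profiles <- function(profiles, params = lre_params()) {
  stopifnot(inherits(params, "lre_params"))
  profiles <- validate_profiles(profiles)
  based <- subtract_baseline(
    profiles,
    baseline_cycles = params$baseline_cycles,
    baseline = params$baseline,
    action = "flag"
  )
  ids <- factor(based$profile_id, levels = unique(based$profile_id))
  rows <- lapply(split(based, ids), analyze_one_profile, params = params)
  dplyr::bind_rows(rows)
}

analyze_one_profile <- function(profile, params) {
  meta_cols <- intersect(c("profile_id", PROFILE_META_COLS), names(profile))
  meta <- profile[1, meta_cols, drop = FALSE]
  base_row <- function(flag, start_cycle = NA_integer_, sel = NULL) {
    out <- meta
    out$baseline <- profile$baseline[1]
    out$flag <- flag
    out$start_cycle <- as.integer(start_cycle)
    out$window_start <- if (!is.null(sel$window)) sel$window$start_cycle else NA_integer_
    out$window_size <- if (!is.null(sel$window)) sel$window$size else NA_integer_
    fit <- sel$fit
    out$emax <- fit$emax %||% NA_real_
    out$delta_e <- fit$delta_e %||% NA_real_
    out$fmax <- fit$fmax %||% NA_real_
    out$r2 <- fit$r2 %||% NA_real_
    out$avg_f0 <- fit$avg_f0 %||% NA_real_
    out$c_half <- fit$c_half %||% NA_real_
    out$stop_reason <- sel$stop_reason %||% NA_character_
    report <- classify_kinetics(profile, fit, sel$window, params = params)
    out$classification <- report$classification
    out$drift_score <- report$drift_score
    out$arc_score <- report$arc_score
    out$fit <- list(fit)
    out$trace <- list(sel$trace)
    out$data <- list(profile)
    out
  }

  flag <- if ("baseline_flag" %in% names(profile)) profile$baseline_flag[1] else NA_character_
  if (!is.na(flag)) {
    return(base_row(flag))
  }
  if (!profile_amplifies(profile, params$baseline_cycles)) {
    return(base_row("non_amplifying"))
  }
  start_cycle <- if (!is.null(params$min_fc)) {
    select_start_cycle_min_fc(profile, params$min_fc)
  } else {
    select_start_cycle_default(profile)
  }
  if (is.na(start_cycle)) {
    return(base_row("no_start_cycle"))
  }
  sel <- expand_window(profile, start_cycle, params)
  base_row(sel$flag, start_cycle = start_cycle, sel = sel)
}

#' Choose the minimum F_C that minimizes replicate F_0 variance
#'
#' Re-analyzes every profile at each candidate minimum fluorescence, computes
#' the run-level average replicate F_0 CV (see [average_replicate_f0_cv()]),
#' and returns the candidate that minimizes it — the program's recommended way
#' of tuning the window bottom: lower the minimum F_C until the replicate CV
#' reaches its minimum. Ties break toward the lower candidate.
#'
#' @param profiles Long-format profile table containing at least one replicate
#'   set (same `run_id`, `sample_name`, `amplicon_name`) with two or more
#'   replicates.
#' @param candidates Numeric vector of candidate minimum-F_C values.
#' @param params An [lre_params()] object (its `min_fc` is replaced by each
#'   candidate in turn).
#' @return A list with `best` (the chosen minimum F_C) and `table` (tibble of
#'   `min_fc`, `av_repl_f0_cv`, `n_sets`).
#' @export
optimize_min_fc <- function(profiles, candidates, params = lre_params()) {
  if (length(candidates) < 1L) abort("`candidates` must contain at least one value.")
  profiles <- validate_profiles(profiles)
  need <- c("run_id", "sample_name", "amplicon_name")
  if (!all(need %in% names(profiles))) {
    abort("Profiles must carry run_id, sample_name and amplicon_name for replicate grouping.")
  }
  evaluate <- function(mfc) {
    p <- params
    p$min_fc <- mfc
    res <- analyze_profiles(profiles, p)
    cvs <- set_f0_cvs(res)
    tibble(
      min_fc = mfc,
      av_repl_f0_cv = if (nrow(cvs)) mean(cvs$f0_cv, na.rm = TRUE) else NA_real_,
      n_sets = sum(is.finite(cvs$f0_cv))
    )
  }
  tab <- dplyr::bind_rows(lapply(sort(candidates), evaluate))
  if (all(!is.finite(tab$av_repl_f0_cv))) {
    abort("No candidate produced any replicate set with a defined F_0 CV.")
  }
  best <- tab$min_fc[which.min(tab$av_repl_f0_cv)] # ties -> lower (sorted)
  list(best = best, table = tab)
}

# Per-replicate-set CV of avg_f0 from an analyze_profiles() result.
set_f0_cvs <- function(analyzed) {
  ok <- analyzed[is.na(analyzed$flag) & is.finite(analyzed$avg_f0), , drop = FALSE]
  if (!nrow(ok)) {
    return(tibble(
      run_id = character(), sample_name = character(),
      amplicon_name = character(), n = integer(), f0_cv = double()
    ))
  }
  dplyr::summarise(
    dplyr::group_by(ok, .data$run_id, .data$sample_name, .data$amplicon_name),
    n = dplyr::n(),
    f0_cv = if (dplyr::n() >= 2) stats::sd(.data$avg_f0) / mean(.data$avg_f0) else NA_real_,
    .groups = "drop"
  )
}
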