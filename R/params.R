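#' Analysis parameters
#'
#' Collects every tunable of the automated analysis in one object. Defaults
#' reproduce the program's standard behaviour: start cycle at the first cycle
#' below the provisional half-maximum cycle, a three-cycle initial window
#' expanded upward while candidate F_0 values stay within 6% of the window
#' average.
#'
#' @param min_fc Optional minimum fluorescence (same arbitrary units as the
#'   readings). When set, the start cycle is the cycle *after* the first cycle
#'   whose baseline-subtracted reading exceeds `min_fc` (that earlier cycle
#'   supplies the start cycle's efficiency denominator). When `NULL` (default)
#'   the half-maximum rule is used.
#' @param f0_threshold Maximum allowed fractional difference between the F_0 of
#'   the candidate cycle above the window and the window-average F_0 before
#'   expansion stops. Default 0.06 (6%).
#' @param initial_window_size Initial window size in cycles; default and
#'   minimum 3.
#' @param baseline_cycles Inclusive cycle range whose mean raw fluorescence
#'   estimates the background; default cycles 4-9, before the amplification
#'   rise under standard cycling.
#' @param baseline Optional fixed baseline (fluorescence units) overriding
#'   estimation from `baseline_cycles`; use 0 for pre-baselined instrument
#'   exports.
#' @param drift_threshold Absolute drift-score bound beyond which post-window
#'   residual trends are classified as plateau drift (positive) or profile
#'   collapse (negative). Default 0.05.
#' @param r2_threshold Minimum window R^2 below which a profile is classified
#'   as arcing. Default 0.9.
#' @param arc_threshold Magnitude of the early-rise efficiency anomaly
#'   (relative disagreement between the E_max implied by the cycles below the
#'   window and the window's E_max) above which a profile is classified as
#'   arcing. Default 0.10.
#' @param low_copy_threshold Molecule count below which the replicate-set
#'   quantity switches to the mean of per-replicate quantities (Poisson
#'   regime). Default 10 molecules.
#' @param c_half_warn_range Warn when replicate C_1/2 values within a set span
#'   more than this many cycles (replicates not tightly clustered). Default 1.
#' @param conv Mass-to-molecules constant for double-stranded DNA
#'   (bp x molecules / ng); see [CONV_DS].
#' @return An object of class `lre_params` (a validated named list).
#' @export
lre_params <- function(min_fc = NULL,
                       f0_threshold = 0.06,
                       initial_window_size = 3L,
                       baseline_cycles = 4:9,
                       baseline = NULL,
                       drift_threshold = 0.05,
                       r2_threshold = 0.9,
                       arc_threshold = 0.10,
                       low_copy_threshold = 10,
                       c_half_warn_range = 1,
                       conv = CONV_DS) {
  if (!is.null(min_fc)) {
    stopifnot(is.numeric(min_fc), length(min_fc) == 1L, is.finite(min_fc), min_fc >= 0)
  }
  stopifnot(
    is.numeric(f0_threshold), length(f0_threshold) == 1L, f0_threshold > 0,
    initial_window_size >= 3,
    is.numeric(baseline_cycles), length(baseline_cycles) >= 1,
    all(baseline_cycles >= 1), !is.unsorted(baseline_cycles),
    drift_threshold > 0, r2_threshold > 0, r2_threshold <= 1,
    arc_threshold > 0, low_copy_threshold > 0, conv > 0
  )
  if (!is.null(baseline)) {
    stopifnot(is.numeric(baseline), length(baseline) == 1L, is.finite(baseline))
  }
  structure(
    list(
      min_fc = min_fc,
      f0_threshold = f0_threshold,
      initial_window_size = as.integer(initial_window_size),
      baseline_cycles = as.integer(baseline_cycles),
      baseline = baseline,
      drift_threshold = drift_threshold,
      r2_threshold = r2_threshold,
      arc_threshold = arc_threshold,
      low_copy_threshold = low_copy_threshold,
      c_half_warn_range = c_half_warn_range,
      conv = conv
    ),
    class = "lre_params"
  )
}

#' @export
print.lre_params <- function(x, ...) {
  cat("<lre_params>\n")
  cat(sprintf("  start-cycle rule : %s\n", if (is.null(x$min_fc)) {
    "first cycle below half-maximum"
  } else {
    sprintf("minimum F_C = %g", x$min_fc)
  }))
  cat(sprintf("  F_0 threshold    : %.1f%%\n", 100 * x$f0_threshold))
  cat(sprintf(
    "  initial window   : %d cycles; baseline cycles %d-%d\n",
    x$initial_window_size, min(x$baseline_cycles), max(x$baseline_cycles)
  ))
  invisible(x)
}
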