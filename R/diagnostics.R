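# Kinetic-anomaly diagnostics. Three pathologies are recognized from the LRE
# plot (ec against fc):
#   plateau drift   - late-cycle points drift progressively ABOVE the fitted
#                     line (amplicon keeps accumulating past the predicted
#                     plateau); including them underestimates E_max and
#                     overestimates quantity.
#   profile collapse- late-cycle points fall BELOW the line (efficiency dies
#                     while the reaction is still amplifying and the profile
#                     stalls under the model plateau); including them
#                     overestimates E_max and underestimates quantity.
#   profile arcing  - the profile bows smoothly away from linear ec-fc
#                     behaviour across the rise (enzyme-formulation artifact).
# Each mode is scored by the statistic that isolates it; a least-squares line
# refitted over distorted cycles absorbs smooth distortions, so collapse and
# arcing are judged against restricted reference fits rather than against the
# (recursively adapted) LRE-window fit. The classifier only annotates;
# excluding aberrant cycles from the analysis is the window selector's job.

#' Post-window residual trend (drift score)
#'
#' For all cycles above the LRE window with defined efficiency, computes the
#' residuals `r_C = ec_C - (emax + delta_e * fc_C)` from the fitted LRE line,
#' fits their slope against cycle number, and reports the *net* residual
#' drift across the post-window region relative to the maximal efficiency:
#' `slope * (cycle span) / emax` (dimensionless). Plateau drift pushes the
#' score strongly positive (the plateau keeps climbing while the fitted line
#' predicts none); a stalled or conforming plateau leaves it near zero.
#'
#' @param profile A single baselined profile (columns `cycle`, `fc`, `ec`).
#' @param fit A valid [fit_lre()] result.
#' @param window The [lre_window()] the fit used.
#' @return The drift score, or `NA` when fewer than 3 eligible cycles exist.
#' @export
post_window_residual_trend <- function(profile, fit, window) {
  stopifnot(inherits(fit, "lre_fit"), inherits(window, "lre_window"))
  if (!fit$valid) {
    return(NA_real_)
  }
  top <- window$start_cycle + window$size - 1L
  post <- profile[profile$cycle > top & is.finite(profile$ec), , drop = FALSE]
  if (nrow(post) < 3L || max(post$cycle) == min(post$cycle)) {
    return(NA_real_)
  }
  r <- post$ec - (fit$emax + fit$delta_e * post$fc)
  x <- post$cycle
  slope <- sum((x - mean(x)) * (r - mean(r))) / sum((x - mean(x))^2)
  slope * (max(x) - min(x)) / fit$emax
}

# Robust plateau level: the fluorescence at the first cycle in the upper half
# of the profile where the efficiency has died (two consecutive cycles with
# ec < 0.05). Unlike the raw maximum this is insensitive to post-plateau
# drift, which keeps inflating the maximum; the upper-half restriction keeps
# noisy near-zero efficiencies of the baseline cycles out of the search.
# Falls back to the profile maximum.
plateau_level <- function(profile) {
  ec <- profile$ec
  mx <- suppressWarnings(max(profile$fc, na.rm = TRUE))
  if (!is.finite(mx) || mx <= 0) {
    return(NA_real_)
  }
  low <- is.finite(ec) & ec < 0.05 & is.finite(profile$fc) & profile$fc >= 0.5 * mx
  i <- which(low & c(low[-1], FALSE))[1]
  if (!is.na(i) && profile$fc[i] > 0) {
    return(profile$fc[i])
  }
  mx
}

# Simple OLS of ec on fc over given rows; returns intercept/slope or NULL.
ec_line <- function(seg) {
  if (nrow(seg) < 3L) {
    return(NULL)
  }
  mx <- mean(seg$fc)
  sxx <- sum((seg$fc - mx)^2)
  if (sxx <= 0) {
    return(NULL)
  }
  slope <- sum((seg$fc - mx) * (seg$ec - mean(seg$ec))) / sxx
  list(intercept = mean(seg$ec) - slope * mx, slope = slope)
}

#' Post-window displacement below the lower-rise reference line (collapse score)
#'
#' Fits a reference LRE line on the window cycles plus up to `n_below` cycles
#' beneath the window — a region that profile collapse (which develops above
#' the half-maximum cycle) leaves clean — and returns the mean residual of
#' the first `n_above` cycles above the window relative to that line, scaled
#' by the reference intercept. Collapse drives the score strongly negative;
#' the recursively refitted window cannot hide it because the reference never
#' includes the collapsing cycles.
#'
#' @param profile A single baselined profile (columns `cycle`, `fc`, `ec`).
#' @param window The selected [lre_window()].
#' @param n_below,n_above Cycles included below / evaluated above the window.
#' @return The displacement score, or `NA` when no post-window cycle with
#'   defined efficiency exists.
#' @export
post_window_displacement <- function(profile, window, n_below = 6L, n_above = 4L) {
  stopifnot(inherits(window, "lre_window"))
  top <- window$start_cycle + window$size - 1L
  lo <- max(2L, window$start_cycle - n_below)
  ref <- profile[profile$cycle >= lo & profile$cycle <= top &
    is.finite(profile$ec) & profile$fc > 0, , drop = FALSE]
  line <- ec_line(ref)
  if (is.null(line) || line$intercept <= 0) {
    return(NA_real_)
  }
  post <- profile[profile$cycle > top & is.finite(profile$ec), , drop = FALSE]
  post <- utils::head(post, n_above)
  if (!nrow(post)) {
    return(NA_real_)
  }
  r <- post$ec - (line$intercept + line$slope * post$fc)
  mean(r) / line$intercept
}

#' Early-rise efficiency anomaly (arcing score)
#'
#' On a model-conforming profile the whole rise lies on one LRE line, so the
#' maximal efficiency implied by the cycles *below* the window equals the one
#' implied by the cycles from the window upward. Smooth arcing bends the
#' efficiency along the profile, and no single line describes it: the
#' intercept of a line through the early-rise cycles (up to `n_below` cycles
#' below the window start, with fluorescence above 1% of the robust plateau)
#' then disagrees with the intercept of the line through the upper profile
#' (window start to plateau, the region arcing leaves clean). The score is
#' the relative disagreement `emax_early / emax_upper - 1`.
#'
#' @param profile A single baselined profile (columns `cycle`, `fc`, `ec`).
#' @param fit A valid [fit_lre()] result.
#' @param window The [lre_window()] the fit used.
#' @param n_below Maximum number of cycles below the window to use.
#' @return The signed anomaly score, or `NA` with fewer than 3 usable
#'   early-rise cycles or fewer than 4 upper cycles.
#' @export
early_rise_anomaly <- function(profile, fit, window, n_below = 6L) {
  stopifnot(inherits(fit, "lre_fit"), inherits(window, "lre_window"))
  if (!fit$valid) {
    return(NA_real_)
  }
  plateau <- plateau_level(profile)
  if (!is.finite(plateau) || plateau <= 0) {
    return(NA_real_)
  }
  early <- profile[
    profile$cycle < window$start_cycle &
      profile$cycle >= window$start_cycle - n_below &
      is.finite(profile$ec) & is.finite(profile$fc) &
      profile$fc >= 0.01 * plateau, ,
    drop = FALSE
  ]
  upper <- profile[
    profile$cycle >= window$start_cycle &
      is.finite(profile$ec) & is.finite(profile$fc) &
      profile$ec >= 0.05 & profile$fc <= 0.97 * plateau, ,
    drop = FALSE
  ]
  if (nrow(early) < 3L || nrow(upper) < 4L) {
    return(NA_real_)
  }
  line_early <- ec_line(early)
  line_upper <- ec_line(upper)
  if (is.null(line_early) || is.null(line_upper) || line_upper$intercept <= 0) {
    return(NA_real_)
  }
  line_early$intercept / line_upper$intercept - 1
}

#' Classify amplification kinetics
#'
#' Produces a kinetics report for one analyzed profile, in order of
#' precedence: `non_amplifying` when there is no valid fit; `plateau_drift`
#' when the post-window residual trend exceeds `params$drift_threshold`;
#' `profile_collapse` when the post-window displacement falls below
#' `-params$drift_threshold`; `arcing` when the early-rise efficiency anomaly
#' exceeds `params$arc_threshold` in magnitude or (for windows of 5+ cycles,
#' where R^2 is meaningful) the window R^2 falls below `params$r2_threshold`;
#' otherwise `conforming`. Each statistic is blind to the other modes by
#' construction: drift lives at the plateau, collapse above the window,
#' arcing below it. All thresholds are configurable via [lre_params()].
#' Classification never alters the quantity — it annotates only.
#'
#' @param profile A single baselined profile (columns `cycle`, `fc`, `ec`).
#' @param fit The [fit_lre()] result for the profile, or `NULL`.
#' @param window The selected [lre_window()], or `NULL`.
#' @param trace Optional window-expansion trace (unused by the default rules;
#'   accepted for interface stability).
#' @param params An [lre_params()] object supplying the thresholds.
#' @return A list of class `lre_kinetics` with elements `classification` (one
#'   of `conforming`, `plateau_drift`, `profile_collapse`, `arcing`,
#'   `non_amplifying`), `drift_score` (signed: positive for drift, negative
#'   for collapse), `arc_score`, `window_r2`, `notes`.
#' @export
classify_kinetics <- function(profile, fit = NULL, window = NULL, trace = NULL,
                              params = lre_params()) {
  report <- function(classification, drift_score = NA_real_,
                     arc_score = NA_real_, window_r2 = NA_real_, notes = NA_character_) {
    structure(
      list(
        classification = classification, drift_score = drift_score,
        arc_score = arc_score, window_r2 = window_r2, notes = notes
      ),
      class = "lre_kinetics"
    )
  }
  if (is.null(fit) || !inherits(fit, "lre_fit") || !fit$valid || is.null(window)) {
    return(report("non_amplifying", notes = "no valid LRE fit"))
  }
  trend <- post_window_residual_trend(profile, fit, window)
  disp <- post_window_displacement(profile, window)
  arc <- early_rise_anomaly(profile, fit, window)
  if (is.finite(trend) && trend > params$drift_threshold) {
    return(report("plateau_drift", trend, arc, fit$r2))
  }
  if (is.finite(disp) && disp < -params$drift_threshold) {
    return(report("profile_collapse", disp, arc, fit$r2))
  }
  if (is.finite(arc) && abs(arc) > params$arc_threshold) {
    return(report("arcing", trend, arc, fit$r2, "early-rise efficiency disagrees with the window"))
  }
  if (window$size >= 5L && is.finite(fit$r2) && fit$r2 < params$r2_threshold) {
    return(report("arcing", trend, arc, fit$r2, "window R^2 below threshold"))
  }
  report("conforming", trend, arc, fit$r2)
}

#' @export
print.lre_kinetics <- function(x, ...) {
  cat(sprintf(
    "<lre_kinetics> %s (drift score %.4g, arc score %.3g, window R2 %.5f)\n",
    x$classification, x$drift_score, x$arc_score, x$window_r2
  ))
  invisible(x)
}
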