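# The sigmoidal LRE model.
#
# Amplification is modelled by a logistic in cycle number C:
#   F_C = F_max / (1 + ((F_max - F_0)/F_0) * (1 + E_max)^(-C))
# whose per-cycle efficiency E_C = F_C/F_{C-1} - 1 satisfies, exactly,
#   E_C = E_max + DeltaE * F_C,   DeltaE = -E_max/F_max.
# LRE estimates (E_max, DeltaE) by ordinary least squares of E_C on F_C over a
# window of cycles in the central region of the profile, then inverts the
# logistic at each window cycle to recover the initial target fluorescence F_0.

#' Per-cycle amplification efficiency
#'
#' Efficiency of a cycle given its fluorescence and the preceding cycle's
#' fluorescence: `fc / fc_prev - 1`, so that perfect doubling gives 1.0 and a
#' plateaued cycle gives 0. Undefined (`NA`) where the denominator is not a
#' positive finite number.
#'
#' @param fc_prev Fluorescence reading of the preceding cycle (baseline
#'   subtracted), arbitrary fluorescence units.
#' @param fc Fluorescence reading of the cycle itself, same units.
#' @return Numeric vector of efficiencies (dimensionless); `NA` where
#'   `fc_prev <= 0` or not finite.
#' @examples
#' cycle_efficiency(200, 400) # 1: perfect doubling
#' cycle_efficiency(400, 400) # 0: plateau
#' @export
cycle_efficiency <- function(fc_prev, fc) {
  out <- fc / fc_prev - 1
  out[!is.finite(fc_prev) | fc_prev <= 0] <- NA_real_
  out
}

#' Predicted fluorescence of the sigmoidal amplification model
#'
#' Forward logistic model: `F_C = fmax / (1 + ((fmax - f0)/f0) * (1 + emax)^-cycle)`.
#' Monotone increasing in `cycle`, equal to `f0` at cycle 0, approaching `fmax`
#' as `cycle` grows.
#'
#' @param f0 Initial target fluorescence (cycle 0), `0 < f0 < fmax`.
#' @param emax Maximal amplification efficiency (dimensionless, > 0); 1.0 is
#'   perfect doubling.
#' @param fmax Plateau fluorescence, fluorescence units.
#' @param cycle Cycle number; may be fractional.
#' @return Predicted fluorescence at `cycle`.
#' @seealso [back_calculate_f0()] for the exact inverse, [c_half_from_fit()].
#' @export
predict_fc <- function(f0, emax, fmax, cycle) {
  stopifnot(all(f0 > 0), all(emax > 0), all(fmax > f0))
  fmax / (1 + ((fmax - f0) / f0) * (1 + emax)^(-cycle))
}

#' Back-calculate initial target fluorescence from one cycle
#'
#' Exact algebraic inverse of [predict_fc()]:
#' `F_0 = fmax / (1 + ((fmax - fc)/fc) * (1 + emax)^cycle)`. Returns `NA` where
#' `fc` is not strictly between 0 and `fmax` (past the usable range the
#' inversion has a pole).
#'
#' @param fc Baseline-subtracted fluorescence reading at `cycle`.
#' @param cycle Cycle number of the reading.
#' @inheritParams predict_fc
#' @return Initial fluorescence `F_0`, or `NA` where undefined.
#' @export
back_calculate_f0 <- function(fc, cycle, emax, fmax) {
  out <- fmax / (1 + ((fmax - fc) / fc) * (1 + emax)^cycle)
  out[!is.finite(fc) | fc <= 0 | fc >= fmax] <- NA_real_
  out
}

#' Fractional cycle at half of plateau fluorescence
#'
#' The model-based C_1/2: the (fractional) cycle at which predicted
#' fluorescence reaches `fmax / 2`, `C_1/2 = log((fmax - f0)/f0) / log(1 + emax)`.
#' A robust profile-position statistic analogous to, but more stable than, Cq.
#'
#' @inheritParams predict_fc
#' @return Fractional cycle number.
#' @examples
#' c_half_from_fit(f0 = 5e6 / 3, emax = 1, fmax = 5e6) # exactly 1 cycle
#' @export
c_half_from_fit <- function(f0, emax, fmax) {
  stopifnot(all(f0 > 0), all(emax > 0), all(fmax > f0))
  log((fmax - f0) / f0) / log(1 + emax)
}

#' Construct an LRE window
#'
#' A contiguous range of cycles used for the efficiency regression,
#' `[start_cycle, start_cycle + size - 1]` inclusive. Cycles are 1-based; the
#' window must start at cycle 2 or later (efficiency is undefined at cycle 1)
#' and contain at least 3 cycles.
#'
#' @param start_cycle First cycle of the window (integer >= 2).
#' @param size Number of cycles in the window (integer >= 3).
#' @return An object of class `lre_window`.
#' @export
lre_window <- function(start_cycle, size) {
  start_cycle <- as.integer(start_cycle)
  size <- as.integer(size)
  if (is.na(start_cycle) || start_cycle < 2L) {
    abort("`start_cycle` must be an integer >= 2 (efficiency is undefined at cycle 1).")
  }
  if (is.na(size) || size < 3L) {
    abort("`size` must be an integer >= 3.")
  }
  structure(list(start_cycle = start_cycle, size = size), class = "lre_window")
}

#' @export
print.lre_window <- function(x, ...) {
  cat(sprintf(
    "<lre_window> cycles %d-%d (%d cycles)\n",
    x$start_cycle, x$start_cycle + x$size - 1L, x$size
  ))
  invisible(x)
}

window_cycles <- function(window) {
  seq.int(window$start_cycle, window$start_cycle + window$size - 1L)
}

#' Fit the LRE regression over a window
#'
#' Ordinary least squares of per-cycle efficiency `ec` on baseline-subtracted
#' fluorescence `fc` over the window cycles. The intercept estimates the
#' maximal efficiency E_max, the slope estimates Delta E (the efficiency lost
#' per fluorescence unit, expected negative), and the plateau is
#' `fmax = -emax/delta_e`. F_0 is back-calculated at every window cycle and
#' averaged; C_1/2 follows from the averaged F_0.
#'
#' A fit with non-negative slope or non-positive intercept describes a
#' non-amplifying or aberrant profile and is flagged invalid (`valid = FALSE`,
#' downstream quantities `NA`); so is a window containing undefined
#' efficiencies.
#'
#' @param profile A baselined profile: data frame with columns `cycle`, `fc`,
#'   `ec` (see [subtract_baseline()]), one profile only.
#' @param window An [lre_window()].
#' @return An object of class `lre_fit`: a list with elements `emax`,
#'   `delta_e`, `fmax`, `r2`, `f0_per_cycle` (named by cycle), `avg_f0`,
#'   `c_half`, `valid`, `window`, and `data` (the window's `(cycle, fc, ec)`
#'   points). Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' prof <- simulate_profile(seed = 1, noise_sd = 0)$profile
#' base <- subtract_baseline(prof)
#' fit_lre(base, lre_window(24, 5))
#' @export
fit_lre <- function(profile, window) {
  stopifnot(is.data.frame(profile), inherits(window, "lre_window"))
  cyc <- window_cycles(window)
  if (max(cyc) > max(profile$cycle)) {
    abort("Window extends past the last cycle of the profile.")
  }
  idx <- match(cyc, profile$cycle)
  fc <- profile$fc[idx]
  ec <- profile$ec[idx]
  pts <- tibble(cycle = cyc, fc = fc, ec = ec)

  if (anyNA(fc) || anyNA(ec)) {
    return(new_lre_fit(window, pts, valid = FALSE, reason = "efficiency undefined within window"))
  }
  # centred OLS; intercept = E_max, slope = DeltaE
  mx <- mean(fc)
  my <- mean(ec)
  sxx <- sum((fc - mx)^2)
  if (sxx <= 0) {
    return(new_lre_fit(window, pts, valid = FALSE, reason = "degenerate window (constant fc)"))
  }
  slope <- sum((fc - mx) * (ec - my)) / sxx
  intercept <- my - slope * mx
  ss_res <- sum((ec - intercept - slope * fc)^2)
  ss_tot <- sum((ec - my)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1

  if (slope >= 0 || intercept <= 0) {
    return(new_lre_fit(window, pts,
      valid = FALSE, emax = intercept, delta_e = slope, r2 = r2,
      reason = "non-amplifying or aberrant fit (delta_e >= 0 or emax <= 0)"
    ))
  }
  fmax <- -intercept / slope
  f0 <- back_calculate_f0(fc, cyc, intercept, fmax)
  avg_f0 <- mean(f0)
  c_half <- if (is.finite(avg_f0) && avg_f0 > 0 && avg_f0 < fmax) {
    c_half_from_fit(avg_f0, intercept, fmax)
  } else {
    NA_real_
  }
  new_lre_fit(window, pts,
    valid = TRUE, emax = intercept, delta_e = slope, fmax = fmax, r2 = r2,
    f0_per_cycle = setNames(f0, cyc), avg_f0 = avg_f0, c_half = c_half
  )
}

new_lre_fit <- function(window, data, valid, emax = NA_real_, delta_e = NA_real_,
                        fmax = NA_real_, r2 = NA_real_, f0_per_cycle = NULL,
                        avg_f0 = NA_real_, c_half = NA_real_, reason = NA_character_) {
  structure(
    list(
      emax = emax, delta_e = delta_e, fmax = fmax, r2 = r2,
      f0_per_cycle = f0_per_cycle, avg_f0 = avg_f0, c_half = c_half,
      valid = valid, reason = reason, window = window, data = data
    ),
    class = "lre_fit"
  )
}

#' @export
print.lre_fit <- function(x, ...) {
  if (!x$valid) {
    cat("<lre_fit> INVALID:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<lre_fit> cycles %d-%d | E_max %.4f | DeltaE %.4g | F_max %.4g | R2 %.5f\n          avg F_0 %.6g | C_1/2 %.2f\n",
    x$window$start_cycle, x$window$start_cycle + x$window$size - 1L,
    x$emax, x$delta_e, x$fmax, x$r2, x$avg_f0, x$c_half
  ))
  invisible(x)
}

#' @describeIn fit_lre per-window-cycle tibble: `cycle`, `fc`, `ec`, fitted
#'   efficiency and `f0`.
#' @param x,object An `lre_fit`.
#' @param ... Unused.
#' @export
tidy.lre_fit <- function(x, ...) {
  out <- x$data
  out$fitted_ec <- if (x$valid) x$emax + x$delta_e * out$fc else NA_real_
  out$f0 <- if (x$valid) unname(x$f0_per_cycle) else NA_real_
  out
}

#' @describeIn fit_lre one-row model summary.
#' @export
glance.lre_fit <- function(x, ...) {
  tibble(
    emax = x$emax, delta_e = x$delta_e, fmax = x$fmax, r2 = x$r2,
    avg_f0 = x$avg_f0, c_half = x$c_half,
    window_start = x$window$start_cycle, window_size = x$window$size,
    valid = x$valid
  )
}
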