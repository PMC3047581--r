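# Independent oracles, coded from first principles and kept separate from the
# package's implementation paths.

# Least squares by the normal equations: solve (X'X) b = X'y directly.
ne_ols <- function(x, y) {
  X <- cbind(1, x)
  b <- solve(t(X) %*% X, t(X) %*% y)
  list(intercept = b[1], slope = b[2])
}

# Straight-line transcription of the start-cycle and window-expansion rules,
# written as plain loops over the baselined readings of one profile.
# Returns list(flag, start, window_start, window_size).
oracle_analyze_window <- function(fc, raw, cycles, baseline_cycles = 4:9,
                                  f0_threshold = 0.06, min_fc = NULL) {
  n <- length(fc)
  ec <- rep(NA_real_, n)
  for (i in 2:n) if (fc[i - 1] > 0) ec[i] <- fc[i] / fc[i - 1] - 1

  # amplification gate: signal above 10x baseline read noise
  noise <- stats::sd(raw[cycles %in% baseline_cycles])
  if (!is.finite(noise)) noise <- 0
  if (!(max(fc) > 10 * noise && max(fc) > 0)) {
    return(list(flag = "non_amplifying"))
  }

  if (is.null(min_fc)) {
    # plateau: mean of cycles within 5% of max (need >= 2); half-max crossing
    # by linear interpolation; start = largest integer strictly below it
    mx <- max(fc)
    pl_idx <- which(fc >= 0.95 * mx)
    if (length(pl_idx) < 2) {
      return(list(flag = "non_amplifying"))
    }
    half <- mean(fc[pl_idx]) / 2
    i <- which(fc >= half)[1]
    if (is.na(i)) {
      return(list(flag = "non_amplifying"))
    }
    h <- if (i == 1) cycles[1] else cycles[i - 1] + (half - fc[i - 1]) / (fc[i] - fc[i - 1])
    start <- floor(h)
    if (start == h) start <- start - 1
    start <- max(2, start)
  } else {
    i <- which(fc > min_fc)[1]
    if (is.na(i) || i >= n) {
      return(list(flag = "no_start_cycle"))
    }
    start <- cycles[i] + 1
  }

  if (start + 2 > n) {
    return(list(flag = "window_truncated", start = start))
  }
  fit_window <- function(lo, hi) {
    b <- ne_ols(fc[lo:hi], ec[lo:hi])
    if (anyNA(c(b$intercept, b$slope))) {
      return(NULL)
    }
    if (b$slope >= 0 || b$intercept <= 0) {
      return(NULL)
    }
    fmax <- -b$intercept / b$slope
    f0 <- fmax / (1 + ((fmax - fc[lo:hi]) / fc[lo:hi]) * (1 + b$intercept)^(lo:hi))
    list(emax = b$intercept, fmax = fmax, avg_f0 = mean(f0))
  }
  lo <- start
  hi <- start + 2
  if (anyNA(ec[lo:hi])) {
    return(list(flag = "aberrant_initial_fit", start = start))
  }
  fit <- fit_window(lo, hi)
  if (is.null(fit)) {
    return(list(flag = "aberrant_initial_fit", start = start))
  }
  repeat {
    cand <- hi + 1
    if (cand > n) break
    if (!is.finite(fc[cand]) || fc[cand] <= 0 || fc[cand] >= 0.999 * fit$fmax) break
    f0c <- fit$fmax / (1 + ((fit$fmax - fc[cand]) / fc[cand]) * (1 + fit$emax)^cand)
    pct <- abs(f0c - fit$avg_f0) / fit$avg_f0
    if (!is.finite(pct) || pct > f0_threshold) break
    new_fit <- if (anyNA(ec[lo:cand])) NULL else fit_window(lo, cand)
    if (is.null(new_fit)) break
    hi <- cand
    fit <- new_fit
  }
  list(flag = NA_character_, start = start, window_start = lo, window_size = hi - lo + 1)
}

# A batch of seeded synthetic profiles mixing all kinetic modes.
mixed_mode_profiles <- function(n_per_mode, seed0 = 5000,
                                modes = c("none", "drift", "collapse", "arcing")) {
  out <- list()
  k <- 0
  for (mode in modes) {
    for (i in seq_len(n_per_mode)) {
      k <- k + 1
      out[[k]] <- simulate_profile(
        n_molecules = 2000, seed = seed0 + k, distortion = mode,
        profile_id = sprintf("%s_%03d", mode, i)
      )
    }
  }
  list(
    profiles = dplyr::bind_rows(lapply(out, `[[`, "profile")),
    truth = dplyr::bind_rows(lapply(out, `[[`, "truth"))
  )
}

# Recurrence-generated noiseless trajectory (self-consistent update), plus its
# exact efficiencies; used as the fit oracle.
recurrence_profile <- function(f0, emax, fmax, n_cycles) {
  f <- numeric(n_cycles)
  prev <- f0
  for (cc in seq_len(n_cycles)) {
    f[cc] <- prev * (1 + emax) / (1 + emax * prev / fmax)
    prev <- f[cc]
  }
  tibble::tibble(
    profile_id = "rec", cycle = seq_len(n_cycles), fluorescence = f,
    fc = f, ec = c(NA, f[-1] / f[-n_cycles] - 1)
  )
}
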