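# Automated LRE-window selection: start-cycle rules and F_0-threshold
# expansion.

test_that("default start cycle is strictly below the half-maximum cycle", {
  # half-max crossing at 5.5 -> start 5
  prof <- tibble::tibble(cycle = 1:9, fc = c(0, 5, 10, 20, 40, 60, 90, 100, 100))
  expect_equal(observed_half_max_cycle(prof), 5.5)
  expect_equal(select_start_cycle_default(prof), 5L)
  # exact integer crossing steps down one further ("strictly below")
  prof2 <- tibble::tibble(cycle = 1:9, fc = c(0, 5, 10, 20, 50, 75, 90, 100, 100))
  expect_equal(observed_half_max_cycle(prof2), 5)
  expect_equal(select_start_cycle_default(prof2), 4L)
  # never below cycle 2
  prof3 <- tibble::tibble(cycle = 1:10, fc = c(60, 80, 95, rep(100, 7)))
  expect_equal(select_start_cycle_default(prof3), 2L)
})

test_that("minimum-F_C start cycle follows the first cycle exceeding the minimum", {
  fc <- c(rep(1e3, 20), 150e3, 260e3, 450e3, 700e3, 900e3, rep(950e3, 5))
  prof <- tibble::tibble(cycle = seq_along(fc), fc = fc)
  # with the minimum set to 225,000 units the first cycle above it is cycle 22,
  # which supplies the efficiency denominator; the start cycle is 23
  expect_equal(select_start_cycle_min_fc(prof, 225e3), 23L)
  expect_equal(select_start_cycle_min_fc(prof, 0), 2L)
  expect_true(is.na(select_start_cycle_min_fc(prof, 1e9)))
  # exceeding only at the final cycle leaves no room for a window
  tail_only <- tibble::tibble(cycle = 1:10, fc = c(rep(0, 9), 10))
  expect_true(is.na(select_start_cycle_min_fc(tail_only, 5)))
})

test_that("start-cycle rules match brute-force transcriptions on random profiles", {
  set.seed(431)
  for (i in 1:50) {
    sim <- simulate_profile(n_molecules = 10^stats::runif(1, 2, 4.5), seed = 6000 + i)
    prof <- subtract_baseline(sim$profile)
    mfc <- stats::runif(1, 1e4, 2e6)
    o <- oracle_analyze_window(prof$fc, prof$fluorescence, prof$cycle, min_fc = mfc)
    got <- select_start_cycle_min_fc(prof, mfc)
    expect_identical(
      as.integer(got),
      as.integer(if (is.null(o$start)) NA else o$start)
    )
  }
})

test_that("window expansion keeps included cycles under the F_0 threshold", {
  sim <- simulate_profile(n_molecules = 3000, seed = 441)
  prof <- subtract_baseline(sim$profile)
  sel <- expand_window(prof, select_start_cycle_default(prof), lre_params())
  tr <- sel$trace
  expect_true(all(tr$pct_diff[tr$included] <= 0.06))
  last <- tr[nrow(tr), ]
  expect_true(!last$included)
  expect_true(is.na(last$pct_diff) || last$pct_diff > 0.06 ||
    sel$stop_reason %in% c("end_of_profile", "fmax_pole"))
  # all window cycles beyond the initial three appear in the trace as included
  expect_equal(sum(tr$included), sel$window$size - 3L)
})

test_that("model-conforming noiseless profiles expand until the plateau pole", {
  sim <- simulate_profile(n_molecules = 2000, seed = 1, noise_sd = 0, noise_floor = 0)
  prof <- subtract_baseline(sim$profile, baseline = sim$truth$baseline)
  sel <- expand_window(prof, select_start_cycle_default(prof), lre_params())
  expect_equal(sel$stop_reason, "fmax_pole")
  expect_true(all(sel$trace$pct_diff[sel$trace$included] < 1e-6))
  expect_gt(sel$window$size, 8)
  # selected-window fit reproduces the generator parameters
  expect_equal(sel$fit$emax, 0.95, tolerance = 1e-8)
  expect_equal(sel$fit$delta_e, -0.95 / 4e6, tolerance = 1e-8)
})

test_that("lowering the F_0 threshold never enlarges the window", {
  for (i in 1:10) {
    sim <- simulate_profile(n_molecules = 2000, seed = 8800 + i)
    prof <- subtract_baseline(sim$profile)
    st <- select_start_cycle_default(prof)
    sizes <- vapply(c(0.12, 0.06, 0.03, 0.01), function(thr) {
      expand_window(prof, st, lre_params(f0_threshold = thr))$window$size
    }, 1L)
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("window selection equals the brute-force rule transcription on mixed profiles", {
  mix <- mixed_mode_profiles(15, seed0 = 7000)
  res <- analyze_profiles(mix$profiles)
  ids <- factor(mix$profiles$profile_id, levels = unique(mix$profiles$profile_id))
  per <- split(subtract_baseline(mix$profiles, action = "flag"), ids)
  for (id in names(per)) {
    prof <- per[[id]]
    o <- oracle_analyze_window(prof$fc, prof$fluorescence, prof$cycle)
    row <- res[res$profile_id == id, ]
    expect_identical(row$flag, o$flag, label = id)
    if (is.na(o$flag)) {
      expect_identical(row$window_start, as.integer(o$window_start), label = id)
      expect_identical(row$window_size, as.integer(o$window_size), label = id)
    }
  }
})

test_that("analysis is deterministic and degenerate inputs are flagged, not fatal", {
  sim <- simulate_profile(n_molecules = 800, seed = 451)
  a1 <- analyze_profiles(sim$profile)
  a2 <- analyze_profiles(sim$profile)
  expect_identical(a1$emax, a2$emax)
  expect_identical(a1$trace[[1]], a2$trace[[1]])

  flat <- tibble::tibble(
    profile_id = "flat", cycle = 1:40,
    fluorescence = rep(0, 40)
  )
  res <- analyze_profiles(flat)
  expect_equal(res$flag, "non_amplifying")
  expect_true(is.na(res$emax))
  expect_equal(res$classification, "non_amplifying")
})

test_that("noiseless analysis recovers the true initial fluorescence", {
  sim <- simulate_profile(n_molecules = 1500, seed = 452, noise_sd = 0, noise_floor = 0)
  # with the background known exactly the inversion is exact
  res <- analyze_profiles(sim$profile, lre_params(baseline = sim$truth$baseline))
  expect_equal(res$avg_f0, sim$truth$f0, tolerance = 1e-6)
  # with the background estimated from early cycles it is recovered to ~0.1%
  res2 <- analyze_profiles(sim$profile)
  expect_equal(res2$avg_f0, sim$truth$f0, tolerance = 2e-3)
})

test_that("minimum-F_C optimization picks the CV-minimizing candidate, ties low", {
  run <- simulate_run(seed = 460)
  profs <- run$profiles
  res <- optimize_min_fc(profs, c(5e4, 2e5, 1e6))
  expect_equal(nrow(res$table), 3)
  expect_equal(res$best, res$table$min_fc[which.min(res$table$av_repl_f0_cv)])
  single <- optimize_min_fc(profs, 2e5)
  expect_equal(single$best, 2e5)
  expect_error(optimize_min_fc(profs, numeric(0)), "at least one")
})
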