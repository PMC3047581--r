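# The synthetic-data generator: ground truth, determinism, localization of
# the injected distortions, Poisson template regime.

test_that("the same seed reproduces a profile bit for bit", {
  a <- simulate_profile(seed = 601)
  b <- simulate_profile(seed = 601)
  expect_identical(a$profile, b$profile)
  expect_identical(a$truth, b$truth)
  c <- simulate_profile(seed = 602)
  expect_false(identical(a$profile$fluorescence, c$profile$fluorescence))
})

test_that("truth records the initial fluorescence implied by the design", {
  sim <- simulate_profile(
    n_molecules = 1000, ocf = 1e5, amplicon_size = 150,
    strandedness = "double", seed = 603, noise_sd = 0
  )
  expect_equal(sim$truth$f0, 1000 * 150 / 9.1e11 * 1e5)
  ss <- simulate_profile(
    n_molecules = 1000, ocf = 1e5, amplicon_size = 150,
    strandedness = "single", seed = 603, noise_sd = 0
  )
  expect_equal(ss$truth$f0, sim$truth$f0 / 2)
})

test_that("noiseless undistorted simulations are fixed points of the analysis", {
  sim <- simulate_profile(n_molecules = 5000, seed = 604, noise_sd = 0, noise_floor = 0)
  res <- analyze_profiles(sim$profile, lre_params(baseline = sim$truth$baseline))
  expect_equal(res$avg_f0, sim$truth$f0, tolerance = 1e-6)
  expect_equal(res$emax, sim$truth$emax, tolerance = 1e-6)
  expect_equal(res$fmax, sim$truth$fmax, tolerance = 1e-4)
})

test_that("distortions are localized away from the early profile", {
  base <- simulate_profile(n_molecules = 2000, seed = 605, noise_sd = 0, noise_floor = 0)
  ch <- c_half_from_fit(base$truth$f0, 0.95, 4e6)
  for (mode in c("drift", "collapse")) {
    dist <- simulate_profile(
      n_molecules = 2000, seed = 605, noise_sd = 0, noise_floor = 0,
      distortion = mode
    )
    pre_mid <- dist$profile$cycle < floor(ch)
    expect_equal(
      dist$profile$fluorescence[pre_mid],
      base$profile$fluorescence[pre_mid],
      tolerance = 1e-12
    )
  }
  # baseline cycles are untouched by every mode (arcing starts above them)
  arc <- simulate_profile(
    n_molecules = 2000, seed = 605, noise_sd = 0, noise_floor = 0,
    distortion = "arcing"
  )
  expect_equal(
    arc$profile$fluorescence[1:9], base$profile$fluorescence[1:9],
    tolerance = 1e-9
  )
})

test_that("drift raises the late plateau and collapse stalls below it", {
  base <- simulate_profile(n_molecules = 2000, seed = 606, noise_sd = 0, noise_floor = 0)
  drift <- simulate_profile(
    n_molecules = 2000, seed = 606, noise_sd = 0,
    noise_floor = 0, distortion = "drift"
  )
  collapse <- simulate_profile(
    n_molecules = 2000, seed = 606, noise_sd = 0,
    noise_floor = 0, distortion = "collapse"
  )
  expect_gt(max(drift$profile$fluorescence), max(base$profile$fluorescence) * 1.1)
  expect_lt(max(collapse$profile$fluorescence) - 5e4, 0.95 * 4e6)
})

test_that("a full run has the designed layout and independent replicate noise", {
  run <- simulate_run(seed = 607)
  expect_equal(dplyr::n_distinct(run$profiles$profile_id), 27)
  expect_equal(dplyr::n_distinct(run$calibration$profile_id), 3)
  sets <- dplyr::distinct(run$profiles, sample_name, amplicon_name)
  expect_equal(nrow(sets), 9)
  # replicates differ only by noise
  r1 <- run$profiles[run$profiles$profile_id == "amp1_S1_r1", "fluorescence"][[1]]
  r2 <- run$profiles[run$profiles$profile_id == "amp1_S1_r2", "fluorescence"][[1]]
  expect_false(identical(r1, r2))
  expect_equal(r1, r2, tolerance = 0.05)
  # two run seeds: different noise, identical truth structure
  run2 <- simulate_run(seed = 608)
  expect_equal(run2$truth$n_molecules, run$truth$n_molecules)
  expect_false(identical(run2$profiles$fluorescence, run$profiles$fluorescence))
})

test_that("low-copy reactions draw integer template counts, including zero", {
  counts <- vapply(1:60, function(i) {
    simulate_profile(n_molecules = 1, seed = 620 + i)$truth$realized_molecules
  }, 1L)
  expect_true(all(counts == floor(counts)))
  expect_true(any(counts == 0))
  expect_true(any(counts >= 2))
  # a zero draw produces a background-only profile
  zero_seed <- 620 + which(counts == 0)[1]
  prof <- simulate_profile(n_molecules = 1, seed = zero_seed)$profile
  expect_lt(max(prof$fluorescence), 5e4 * 1.05)
  # stochastic output without a seed is refused
  expect_error(simulate_profile(n_molecules = 1), "seed")
})
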