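# Absolute quantification: average profiles, optical calibration, molecule
# conversion, the low-copy replicate rule and the replicate-variance
# statistics.

two_replicates <- function() {
  tibble::tibble(
    profile_id = rep(c("a", "b"), each = 12),
    run_id = "r1", sample_name = "s", amplicon_name = "g",
    amplicon_size = 150L, strandedness = "double", is_calibration = FALSE,
    cycle = rep(1:12, 2),
    fluorescence = c(100 * 1:12, 300 * 1:12)
  )
}

test_that("average profile is the per-cycle mean with inherited annotations", {
  avg <- make_average_profile(two_replicates())
  expect_equal(avg$fluorescence, 200 * 1:12)
  expect_equal(unique(avg$sample_name), "s")
  expect_equal(unique(avg$amplicon_size), 150L)
  # averaging identical replicates is idempotent
  reps <- two_replicates()
  reps$fluorescence <- rep(100 * 1:12, 2)
  expect_equal(make_average_profile(reps)$fluorescence, 100 * 1:12)
})

test_that("averaging rejects mismatched replicate sets", {
  reps <- two_replicates()
  expect_error(make_average_profile(reps[reps$profile_id == "a", ]), "at least 2")
  ragged <- reps[-3, ]
  expect_error(make_average_profile(ragged), "cycle grid")
  mixed <- reps
  mixed$amplicon_name[mixed$profile_id == "b"] <- "other"
  expect_error(make_average_profile(mixed), "amplicon_name")
})

test_that("replicate averaging shrinks read noise like the square root of k", {
  truth <- simulate_profile(n_molecules = 4000, seed = 470, noise_sd = 0)$profile
  k <- 8
  reps <- dplyr::bind_rows(lapply(1:k, function(r) {
    p <- simulate_profile(n_molecules = 4000, seed = 470 + r)$profile
    p$profile_id <- paste0("r", r)
    p
  }))
  avg <- make_average_profile(reps)
  plateau_cycles <- 35:50
  res_avg <- (avg$fluorescence - truth$fluorescence)[plateau_cycles] /
    truth$fluorescence[plateau_cycles]
  expect_lt(stats::sd(res_avg), 2 * 0.004 / sqrt(k))
})

test_that("OCF is initial fluorescence per known nanogram, averaged over profiles", {
  fake <- tibble::tibble(
    profile_id = c("c1", "c2"), flag = NA_character_,
    avg_f0 = c(1e4, 1.2e4), known_ng = 0.1
  )
  ocf <- compute_ocf(fake)
  expect_equal(ocf$value, mean(c(1e5, 1.2e5)))
  expect_equal(ocf$n, 2)
  # doubling fluorescence doubles the OCF
  fake2 <- fake
  fake2$avg_f0 <- fake2$avg_f0 * 2
  expect_equal(compute_ocf(fake2)$value, 2 * ocf$value)
  # flagged profiles are excluded; all flagged is an error
  fake$flag[1] <- "non_amplifying"
  expect_equal(compute_ocf(fake)$n, 1)
  fake$flag[2] <- "non_amplifying"
  expect_error(compute_ocf(fake), "No calibration profile")
})

test_that("calibration built with a known OCF recovers it", {
  truth_ocf <- 1e5
  cal <- simulate_run(seed = 480, noise_sd = 0, noise_floor = 0)$calibration
  res <- analyze_profiles(cal)
  ocf <- compute_ocf(res)
  expect_equal(ocf$value, truth_ocf, tolerance = 1e-3)
  # and exactly when the background is known
  res2 <- analyze_profiles(cal, lre_params(baseline = 5e4))
  expect_equal(compute_ocf(res2)$value, truth_ocf, tolerance = 1e-6)
})

test_that("mass-to-molecule conversion uses 9.1e11 bp molecules per ng", {
  # 1 ng of a 100 bp double-stranded amplicon
  expect_equal(molecules_from_f0(1, ocf = 1, amplicon_size = 100), 9.1e9)
  # single-stranded targets carry twice the molecules per nanogram
  expect_equal(
    molecules_from_f0(1, 1, 100, "single"),
    2 * molecules_from_f0(1, 1, 100, "double")
  )
  # molecules scale inversely with amplicon size at fixed mass
  expect_equal(
    molecules_from_f0(1, 1, 50) / molecules_from_f0(1, 1, 200), 4
  )
})

test_that("low-copy replicate sets are quantified by per-replicate averaging", {
  ocf <- 1e5
  # three replicates with 2, 6 and 7 template molecules (no Poisson draw so
  # the counts are exact)
  profs <- dplyr::bind_rows(lapply(seq_along(c(2, 6, 7)), function(i) {
    simulate_profile(
      n_molecules = c(2, 6, 7)[i], poisson = FALSE, noise_sd = 0, noise_floor = 0,
      profile_id = paste0("p", i), sample_name = "lc", amplicon_name = "g",
      run_id = "r1"
    )$profile
  }))
  q <- suppressWarnings(quantify_replicates(profs, ocf, lre_params(baseline = 5e4)))
  expect_equal(q$path, "replicate_mean")
  expect_equal(q$flag, "poisson_regime")
  expect_equal(q$molecules, 5, tolerance = 1e-4)
  expect_equal(sort(q$replicates[[1]]$molecules), c(2, 6, 7), tolerance = 1e-4)

  # a high-copy set takes the average-profile path
  hi <- dplyr::bind_rows(lapply(1:3, function(i) {
    simulate_profile(
      n_molecules = 1000, noise_sd = 0, noise_floor = 0,
      profile_id = paste0("h", i), sample_name = "hc", amplicon_name = "g",
      run_id = "r1"
    )$profile
  }))
  qh <- quantify_replicates(hi, ocf, lre_params(baseline = 5e4))
  expect_equal(qh$path, "average_profile")
  expect_true(is.na(qh$flag))
  expect_equal(qh$molecules, 1000, tolerance = 1e-5)
})

test_that("replicate F_0 CV matches hand computation", {
  expect_equal(replicate_f0_cv(c(90, 110)), sqrt(200) / 100)
  expect_equal(replicate_f0_cv(c(90, 110)), 0.1414, tolerance = 1e-3)
  expect_equal(replicate_f0_cv(c(5, 5, 5)), 0)
  expect_true(is.na(replicate_f0_cv(42)))
})

test_that("run-level CV averages the defined set CVs", {
  expect_equal(average_replicate_f0_cv(c(0.10, 0.20)), 0.15)
  expect_equal(average_replicate_f0_cv(0.3), 0.3)
  expect_equal(average_replicate_f0_cv(c(0.1, NA, 0.3)), 0.2)
  expect_true(is.na(average_replicate_f0_cv(NA_real_)))
})

test_that("run statistics agree with flat recomputation and ignore ordering", {
  run <- simulate_run(seed = 490)
  ana <- analyze_profiles(run$profiles)
  q <- suppressWarnings(quantify_replicates(run$profiles, 1e5, analyzed = ana))
  # flat recomputation from per-replicate F_0 values grouped by set
  ok <- ana[is.na(ana$flag), ]
  flat <- vapply(
    split(ok$avg_f0, paste(ok$run_id, ok$sample_name, ok$amplicon_name)),
    replicate_f0_cv, 1.0
  )
  expect_equal(average_replicate_f0_cv(q$f0_cv), mean(flat[is.finite(flat)]),
    tolerance = 1e-12
  )
  # shuffling profile order changes nothing
  set.seed(1)
  shuffled <- run$profiles[sample(nrow(run$profiles)), ]
  shuffled <- dplyr::arrange(shuffled, profile_id, cycle)
  q2 <- suppressWarnings(quantify_replicates(shuffled, 1e5))
  expect_equal(sort(q2$f0_cv), sort(q$f0_cv), tolerance = 1e-12)
  expect_equal(
    average_replicate_f0_cv(q2$f0_cv), average_replicate_f0_cv(q$f0_cv),
    tolerance = 1e-12
  )
})

test_that("widely spread replicates trigger the clustering warning", {
  a <- simulate_profile(n_molecules = 500, seed = 495, profile_id = "a", sample_name = "s", amplicon_name = "g")$profile
  b <- simulate_profile(n_molecules = 4000, seed = 496, profile_id = "b", sample_name = "s", amplicon_name = "g")$profile
  expect_warning(
    quantify_replicates(dplyr::bind_rows(a, b), 1e5),
    "not tightly clustered"
  )
})
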