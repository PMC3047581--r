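# The sigmoidal model primitives and the LRE regression.

test_that("cycle efficiency is the consecutive-reading ratio minus one", {
  expect_equal(cycle_efficiency(200, 400), 1) # perfect doubling
  expect_equal(cycle_efficiency(400, 400), 0) # plateau
  expect_true(is.na(cycle_efficiency(0, 100)))
  expect_true(is.na(cycle_efficiency(-5, 100)))
  expect_equal(cycle_efficiency(c(100, 200), c(150, 250)), c(0.5, 0.25))
})

test_that("forward model hits its boundary values", {
  expect_equal(predict_fc(1e-3, 0.95, 5e6, 0), 1e-3)
  expect_equal(predict_fc(2.5e6, 0.9, 5e6, 0), 2.5e6) # f0 = fmax/2 at C = 0
  expect_equal(predict_fc(1e-3, 0.95, 5e6, 1e3), 5e6, tolerance = 1e-6)
  # monotone increasing in cycle
  fc <- predict_fc(1e-3, 0.95, 5e6, 0:50)
  expect_true(all(diff(fc) > 0))
})

test_that("back-calculation inverts the forward model exactly", {
  expect_equal(back_calculate_f0(1e-3, 0, 0.95, 5e6), 1e-3) # zero-cycle identity
  fc25 <- predict_fc(1e-3, 0.95, 5e6, 25)
  expect_equal(back_calculate_f0(fc25, 25, 0.95, 5e6), 1e-3, tolerance = 1e-9)
  expect_true(is.na(back_calculate_f0(5e6, 10, 0.95, 5e6))) # at the pole
  expect_true(is.na(back_calculate_f0(0, 10, 0.95, 5e6)))
})

test_that("round-trip inversion holds across random parameter tuples", {
  set.seed(401)
  n <- 1000
  f0 <- 10^stats::runif(n, -6, 2)
  emax <- stats::runif(n, 0.4, 1.0)
  fmax <- 10^stats::runif(n, 5, 7)
  cyc <- stats::runif(n, 0, 45)
  fc <- predict_fc(f0, emax, fmax, cyc)
  # the inversion is defined on the usable range, away from the plateau pole
  ok <- fc > 1e-12 * fmax & fc < 0.99 * fmax
  expect_gt(sum(ok), 500)
  got <- back_calculate_f0(fc[ok], cyc[ok], emax[ok], fmax[ok])
  expect_true(all(abs(got / f0[ok] - 1) <= 1e-9))
})

test_that("half-maximum cycle has its closed form and defining property", {
  expect_equal(c_half_from_fit(5e6 / 3, 1, 5e6), 1) # ln(2)/ln(2)
  ch <- c_half_from_fit(1e-3, 0.87, 4e6)
  expect_equal(predict_fc(1e-3, 0.87, 4e6, ch), 2e6, tolerance = 1e-9)
  # strictly decreasing in f0
  f0s <- 10^seq(-4, 1, length.out = 30)
  expect_true(all(diff(c_half_from_fit(f0s, 0.9, 4e6)) < 0))
})

test_that("LRE fit recovers a line through exact points", {
  fc <- c(1e5, 2e5, 3e5)
  prof <- tibble::tibble(cycle = 2:4, fc = fc, ec = 1.0 - 2e-7 * fc)
  fit <- fit_lre(prof, lre_window(2, 3))
  expect_true(fit$valid)
  expect_equal(fit$emax, 1.0, tolerance = 1e-12)
  expect_equal(fit$delta_e, -2e-7, tolerance = 1e-12)
  expect_equal(fit$fmax, 5e6, tolerance = 1e-9)
  expect_equal(fit$r2, 1.0, tolerance = 1e-12)
})

test_that("recurrence-generated profiles give exactly collinear points and exact recovery", {
  prof <- recurrence_profile(f0 = 0.02, emax = 0.9, fmax = 1e6, n_cycles = 45)
  # efficiency equals emax * (1 - fc/fmax) at machine precision
  idx <- 2:45
  expect_equal(prof$ec[idx], 0.9 * (1 - prof$fc[idx] / 1e6), tolerance = 1e-12)
  # any >= 3-cycle window in the rise recovers the generator parameters
  for (w in list(c(15, 3), c(10, 8), c(20, 6))) {
    fit <- fit_lre(prof, lre_window(w[1], w[2]))
    expect_equal(fit$emax, 0.9, tolerance = 1e-10)
    expect_equal(fit$delta_e, -0.9 / 1e6, tolerance = 1e-10)
    # back-calculated f0 identical across window cycles
    expect_lt(diff(range(fit$f0_per_cycle)) / fit$avg_f0, 1e-9)
    expect_equal(fit$avg_f0, 0.02, tolerance = 1e-9)
  }
})

test_that("LRE fit equals an independent normal-equations oracle on noisy points", {
  set.seed(402)
  fc <- sort(stats::runif(8, 1e5, 3e6))
  ec <- 0.95 - 2.4e-7 * fc + stats::rnorm(8, 0, 0.01)
  prof <- tibble::tibble(cycle = 2:9, fc = fc, ec = ec)
  fit <- fit_lre(prof, lre_window(2, 8))
  oracle <- ne_ols(fc, ec)
  expect_equal(fit$emax, oracle$intercept, tolerance = 1e-10)
  expect_equal(fit$delta_e, oracle$slope, tolerance = 1e-10)
})

test_that("non-amplifying and aberrant windows are flagged, not quantified", {
  prof <- tibble::tibble(cycle = 2:5, fc = c(1, 2, 3, 4) * 1e5, ec = c(0.1, 0.2, 0.3, 0.4))
  fit <- fit_lre(prof, lre_window(2, 4)) # efficiency rising with fluorescence
  expect_false(fit$valid)
  expect_true(is.na(fit$avg_f0))
  prof2 <- tibble::tibble(cycle = 2:4, fc = 1:3, ec = c(NA, 0.5, 0.4))
  expect_false(fit_lre(prof2, lre_window(2, 3))$valid)
})

test_that("efficiencies are scale-free and fitted scale parameters scale with k", {
  prof <- recurrence_profile(0.05, 0.85, 2e6, 45)
  k <- 137.5
  scaled <- prof
  scaled$fc <- prof$fc * k
  scaled$ec <- c(NA, scaled$fc[-1] / scaled$fc[-45] - 1)
  expect_equal(scaled$ec[2:45], prof$ec[2:45], tolerance = 1e-12)
  f1 <- fit_lre(prof, lre_window(12, 6))
  f2 <- fit_lre(scaled, lre_window(12, 6))
  expect_equal(f2$emax, f1$emax, tolerance = 1e-9)
  expect_equal(f2$fmax, f1$fmax * k, tolerance = 1e-6)
  expect_equal(f2$avg_f0, f1$avg_f0 * k, tolerance = 1e-6)
})

test_that("tidy and glance summarise a fit", {
  prof <- recurrence_profile(0.05, 0.85, 2e6, 45)
  fit <- fit_lre(prof, lre_window(12, 5))
  td <- tidy(fit)
  expect_equal(nrow(td), 5)
  expect_named(td, c("cycle", "fc", "ec", "fitted_ec", "f0"))
  gl <- glance(fit)
  expect_equal(gl$window_start, 12L)
  expect_true(gl$valid)
})
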