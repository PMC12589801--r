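# The measurement chain: thresholding, peak extraction, calibration fitting,
# lineal-energy conversion, binning, and uncertainty propagation.

test_that("noise threshold is mean + k sd of the baseline", {
  set.seed(12)
  base <- osc_trace(rnorm(50000, 2, 0.5))
  expect_lt(abs(determine_threshold(base, k = 5) - 4.5), 0.05)
  expect_equal(determine_threshold(base, k = 0), mean(base$samples))
  expect_equal(determine_threshold(osc_trace(rep(0, 100)), k = 5), 0)
  # constant non-zero baseline: threshold equals the constant
  expect_equal(determine_threshold(osc_trace(rep(3, 100)), k = 5), 3)
})

test_that("peak extraction finds injected pulses and applies the tie-break", {
  v <- rep(0, 200)
  v[100:103] <- c(60, 120, 80, 30)
  tr <- osc_trace(v)
  pk <- extract_peaks(tr, threshold = 10, min_separation = 10)
  expect_equal(pk$values, 120)
  # two pulses closer than min_separation: the larger wins
  v2 <- rep(0, 200)
  v2[100] <- 120; v2[105] <- 90
  pk2 <- extract_peaks(osc_trace(v2), threshold = 10, min_separation = 10)
  expect_equal(pk2$values, 120)
  # far enough apart, both survive
  v3 <- rep(0, 200)
  v3[100] <- 120; v3[150] <- 90
  pk3 <- extract_peaks(osc_trace(v3), threshold = 10, min_separation = 10)
  expect_equal(sort(pk3$values), c(90, 120))
  # full-scale pulse is recorded and flagged saturated
  v4 <- rep(0, 200); v4[100] <- 500
  pk4 <- extract_peaks(osc_trace(v4), threshold = 10, full_scale = 500)
  expect_equal(pk4$values, 500)
  expect_equal(pk4$saturated_count, 1L)
  # nothing above threshold
  expect_equal(length(extract_peaks(osc_trace(rep(0.1, 50)), 10)), 0L)
})

test_that("calibration fit is exact on noiseless quantiles", {
  ref <- reference_spectrum(target = 2.13)
  # a sample whose type-7 empirical quantiles coincide with the theoretical
  # ones: values at q((i-1)/(n-1)), finite endpoints
  n <- 5000
  u <- seq(0, 1, length.out = n)
  u[1] <- 1e-9; u[n] <- 0.9999
  pk <- event_list(ref$q(u), "mV")
  cal <- fit_calibration(pk, ref)
  expect_equal(cal$a, 1, tolerance = 1e-6)
  expect_equal(cal$b, 0, tolerance = 1e-6)
  # affine transformation of the same quantiles is recovered exactly
  a0 <- 0.016; b0 <- 0.2
  pk2 <- event_list(pmax((ref$q(u) - b0) / a0, 0), "mV")
  cal2 <- fit_calibration(pk2, ref)
  expect_equal(cal2$a, a0, tolerance = 1e-6)
  expect_equal(cal2$b, b0, tolerance = 1e-4)
  expect_error(fit_calibration(event_list(rep(5, 200), "mV"), ref),
               "degenerate")
})

test_that("calibration recovery under sampling noise is unbiased and tightens with n", {
  ref <- reference_spectrum(target = 2.13)
  a0 <- 0.016; b0 <- 0.2
  fit_once <- function(n, seed) {
    set.seed(seed)
    pk <- event_list(pmax((ref$r(n) - b0) / a0, 0), "mV")
    fit_calibration(pk, ref)
  }
  cals <- lapply(1:30, function(s) fit_once(2000, s))
  a_hat <- vapply(cals, `[[`, numeric(1), "a")
  b_hat <- vapply(cals, `[[`, numeric(1), "b")
  # bias far below the spread across replicates
  expect_lt(abs(mean(a_hat) - a0), 2 * stats::sd(a_hat) / sqrt(30))
  expect_lt(abs(mean(b_hat) - b0), 3 * stats::sd(b_hat) / sqrt(30))
  # reported slope uncertainty shrinks with sample size
  u_small <- mean(vapply(1:10, function(s) fit_once(500, s)$u_a, numeric(1)))
  u_large <- mean(vapply(1:10, function(s) fit_once(20000, s)$u_a, numeric(1)))
  expect_lt(u_large, u_small)
})

test_that("lineal-energy conversion applies the affine map and drops non-positives", {
  pk <- event_list(c(0, 50, 100), "mV")
  cal <- calibration_model(a = 0.02, b = 0.1)
  out <- convert_to_lineal(pk, cal)
  expect_equal(out$values, c(0.1, 1.1, 2.1))
  expect_equal(out$unit, "keV/um")
  # identity calibration
  cal1 <- calibration_model(a = 1, b = 0)
  out1 <- convert_to_lineal(event_list(c(2, 5), "mV"), cal1)
  expect_equal(out1$values, c(2, 5))
  # P = 0 with b = 0 yields y = 0, dropped and counted
  out0 <- convert_to_lineal(event_list(c(0, 10), "mV"), cal1)
  expect_equal(out0$values, 10)
  expect_equal(out0$dropped_count, 1L)
  # negative results under a negative intercept are dropped too
  outn <- convert_to_lineal(event_list(c(1, 100), "mV"),
                            calibration_model(a = 0.02, b = -0.5))
  expect_equal(length(outn), 1L)
  expect_equal(outn$dropped_count, 1L)
})

test_that("binning uses half-open 0.5 keV/um bins with overflow", {
  sp <- bin_spectrum(c(0.74, 20.3, 0.1, 19.99))
  expect_equal(length(sp$counts), 40L)
  expect_equal(sp$bin_edges, seq(0, 20, by = 0.5))
  expect_equal(sp$counts[2], 1L)          # 0.74 in [0.5, 1.0)
  expect_equal(sp$counts[1], 1L)          # 0.1 in [0, 0.5)
  expect_equal(sp$counts[40], 1L)         # 19.99 in [19.5, 20)
  expect_equal(sp$overflow_count, 1L)     # 20.3 overflows
  expect_equal(sp$overflow_values, 20.3)
  # boundary values land in the bin whose low edge they equal
  spb <- bin_spectrum(c(0.5, 1.0, 20.0))
  expect_equal(spb$counts[2], 1L)
  expect_equal(spb$counts[3], 1L)
  expect_equal(spb$overflow_count, 1L)
})

test_that("binning conserves counts for arbitrary event lists", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample.int(2000, 1)
    y <- rlnorm(n, meanlog = runif(1, 0, 2.5), sdlog = runif(1, 0.2, 1))
    sp <- bin_spectrum(y)
    expect_identical(sum(sp$counts) + sp$overflow_count, length(y))
    expect_identical(sp$n, length(y))
  }
})

test_that("calibration-uncertainty propagation has the right limits", {
  ref <- reference_spectrum(target = 8)
  set.seed(33)
  pk <- event_list((ref$r(20000) - 0.2) / 0.04, "mV")
  # no uncertainty, no spread
  cal0 <- calibration_model(a = 0.04, b = 0.2, u_a = 0, u_b = 0)
  expect_equal(propagate_calibration_uncertainty(cal0, pk)$relative_sd, 0)
  # b = 0, u_b = 0: the dose average is degree-1 homogeneous in a, so the
  # relative spread equals u_a / a
  calh <- calibration_model(a = 0.04, b = 0, u_a = 0.0012, u_b = 0)
  prop <- propagate_calibration_uncertainty(calh, pk, n_mc = 4000, seed = 2)
  expect_equal(prop$relative_sd, 0.0012 / 0.04, tolerance = 0.05)
  expect_error(propagate_calibration_uncertainty(calh, pk, n_mc = 10),
               "at least 100")
})

test_that("mid-range coefficient uncertainties propagate to about 3 percent", {
  # Bragg-peak-like spectrum; slope uncertainty 3%, intercept 0.15 keV/um
  ref <- reference_spectrum(target = 8)
  set.seed(44)
  pk <- event_list((ref$r(20000) - 0.2) / 0.04, "mV")
  cal <- calibration_model(a = 0.04, b = 0.2, u_a = 0.03 * 0.04, u_b = 0.15)
  prop <- propagate_calibration_uncertainty(cal, pk, n_mc = 3000, seed = 6)
  expect_equal(round(100 * prop$relative_sd), 3)
})
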