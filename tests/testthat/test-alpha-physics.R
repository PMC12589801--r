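# Range-energy interpolation, material equivalence, gap transmission,
# residual energy, and lineal-energy conversion for alpha particles.

test_that("range interpolation reproduces anchors and linear midpoints", {
  expect_equal(interpolate_range(6.0, pmma), 45)
  expect_equal(interpolate_range(5.0, pmma), 33)
  # midway between the 45 and 58 um anchors
  expect_equal(interpolate_range(6.5, pmma), 51.5)
  # vectorised
  expect_equal(interpolate_range(c(5, 8), pmma), c(33, 73))
  expect_error(interpolate_range(0, pmma), "positive")
  expect_error(interpolate_range(-1, pmma), "positive")
})

test_that("power-law extrapolation is continuous and monotone beyond anchors", {
  e <- seq(0.5, 12, by = 0.01)
  r <- interpolate_range(e, pmma)
  expect_true(all(diff(r) > 0))
  expect_true(all(r > 0))
  # continuity at the anchor boundaries
  expect_equal(interpolate_range(5 - 1e-9, pmma), 33, tolerance = 1e-6)
  expect_equal(interpolate_range(8 + 1e-9, pmma), 73, tolerance = 1e-6)
})

test_that("range inversion matches anchors and linear segments", {
  expect_equal(invert_range(33, pmma), 5.0)
  expect_equal(invert_range(73, pmma), 8.0)
  # between the 33 um / 5 MeV and 45 um / 6 MeV anchors
  expect_equal(invert_range(37, pmma), 5 + 4 / 12, tolerance = 1e-12)
  expect_gt(invert_range(37, pmma), 5.3)  # conservative gap threshold
  expect_error(invert_range(0, pmma), "positive")
})

test_that("interpolate_range and invert_range are mutual inverses", {
  e <- seq(5, 8, length.out = 101)
  expect_equal(invert_range(interpolate_range(e, pmma), pmma), e,
               tolerance = 1e-9)
  # and outside the anchor domain, through the power-law branches
  e_out <- c(1, 3, 4.5, 9, 11)
  expect_equal(invert_range(interpolate_range(e_out, pmma), pmma), e_out,
               tolerance = 1e-9)
  r <- seq(20, 90, length.out = 51)
  expect_equal(interpolate_range(invert_range(r, pmma), pmma), r,
               tolerance = 1e-9)
})

test_that("range_table validates its anchors", {
  expect_error(range_table(c(5, 6), c(45, 33)), "strictly increasing")
  expect_error(range_table(c(6, 5), c(33, 45)), "strictly increasing")
  expect_error(range_table(5, 33), "two")
  expect_error(range_table(c(5, 6), c(33, 45), density = -1), "positive")
})

test_that("mass-thickness equivalence matches the window-conversion figures", {
  # 40 um LDPE (0.92) -> PMMA (1.18) and water (1.00)
  expect_equal(round(equivalent_thickness(40, 0.92, 1.18)), 31)
  expect_equal(round(equivalent_thickness(40, 0.92, 1.00)), 37)
  expect_equal(equivalent_thickness(40, 0.92, 1.00), 36.8)
  # identity and exact round trip
  expect_equal(equivalent_thickness(17.3, 1.18, 1.18), 17.3)
  expect_equal(
    equivalent_thickness(equivalent_thickness(25, 0.92, 2.33), 2.33, 0.92),
    25, tolerance = 1e-15)
  expect_error(equivalent_thickness(-1, 1, 1), "positive")
})

test_that("alpha energy sampling respects bounds, moments and determinism", {
  m <- alpha_spectrum_model("uniform")
  s <- sample_alpha_energies(m, 1e6, seed = 42)
  expect_true(all(s > 0 & s <= 8.68))
  se <- 8.68 / sqrt(12) / sqrt(1e6)
  expect_lt(abs(mean(s) - 8.68 / 2), 3 * se)
  expect_identical(sample_alpha_energies(m, 100, seed = 7),
                   sample_alpha_energies(m, 100, seed = 7))
  expect_identical(sample_alpha_energies(m, 0, seed = 1), numeric(0))
  expect_error(sample_alpha_energies(m, -1), "non-negative")
  # three-body phase space: mean e_max/2 by symmetry, support respected
  m3 <- alpha_spectrum_model("three_body")
  s3 <- sample_alpha_energies(m3, 2e5, seed = 42)
  expect_true(all(s3 > 0 & s3 <= 8.68))
  expect_lt(abs(mean(s3) - 8.68 / 2), 0.02)
  # tabulated spectrum drawn back through the inverse CDF
  mt <- alpha_spectrum_model("custom_tabulated", tab = data.frame(
    energy = c(1, 4, 8), weight = c(0, 1, 0)))
  st <- sample_alpha_energies(mt, 2e5, seed = 42)
  expect_true(all(st > 0 & st <= 8.68))
})

test_that("transmission fraction: closed form, monotonicity, limits", {
  m <- alpha_spectrum_model("uniform")
  expect_equal(transmission_fraction(m, gap_geometry(0), pmma), 1)
  # uniform closed form at the 5 MeV / 33 um anchor
  expect_equal(transmission_fraction(m, gap_geometry(33), pmma),
               (8.68 - 5) / 8.68, tolerance = 1e-12)
  # beyond the endpoint range
  far <- interpolate_range(8.68, pmma) + 1
  expect_equal(transmission_fraction(m, gap_geometry(far), pmma), 0)
  # closed form vs generic quadrature across gaps
  gaps <- c(10, 25, 33, 40, 50, 60)
  tf <- vapply(gaps, function(g)
    transmission_fraction(m, gap_geometry(g), pmma), numeric(1))
  closed <- pmax(0, (8.68 - invert_range(gaps, pmma)) / 8.68)
  expect_equal(tf, closed, tolerance = 1e-6)
  expect_true(all(diff(tf) <= 0))
  # non-uniform kinds are monotone too and agree with Monte Carlo
  m3 <- alpha_spectrum_model("three_body")
  tf3 <- vapply(gaps, function(g)
    transmission_fraction(m3, gap_geometry(g), pmma), numeric(1))
  expect_true(all(diff(tf3) <= 0))
  e_mc <- sample_alpha_energies(m3, 2e5, seed = 5)
  mc <- mean(interpolate_range(e_mc, pmma) > 40)
  expect_lt(abs(tf3[4] - mc), 0.01)
})

test_that("window layers fold into the effective barrier by mass thickness", {
  m <- alpha_spectrum_model("uniform")
  # 40 um LDPE window alone ~ 31.2 um PMMA
  g_win <- gap_geometry(0, window_layers = data.frame(thickness = 40,
                                                      density = 0.92))
  g_direct <- gap_geometry(equivalent_thickness(40, 0.92, 1.18))
  expect_equal(transmission_fraction(m, g_win, pmma),
               transmission_fraction(m, g_direct, pmma), tolerance = 1e-12)
})

test_that("residual energy conserves range across the gap", {
  # 73 - 40 = 33 um residual range -> the 5 MeV anchor
  expect_equal(residual_energy(8.0, gap_geometry(40), pmma), 5.0,
               tolerance = 1e-9)
  expect_equal(residual_energy(6.3, gap_geometry(0), pmma), 6.3)
  expect_true(is.na(residual_energy(5.0, gap_geometry(50), pmma)))
  # invariant R(E_out) + gap = R(E_in)
  e_in <- seq(5.5, 8.5, by = 0.25)
  g <- gap_geometry(30)
  e_out <- residual_energy(e_in, g, pmma)
  expect_equal(interpolate_range(e_out, pmma) + 30,
               interpolate_range(e_in, pmma), tolerance = 1e-6)
})

test_that("empirical alpha lineal energies stay inside configured bounds", {
  det <- detector_model()
  y <- alpha_event_lineal_energy(runif(500, 5, 8), det, mode = "empirical",
                                 y_lo = 8, y_hi = 20, seed = 3)
  expect_true(all(y >= 8 & y <= 20))
  expect_error(alpha_event_lineal_energy(6, det, y_lo = 5, y_hi = 5),
               "y_lo < y_hi")
})

test_that("physics-mode lineal energy matches the brute-force slowing oracle", {
  det <- detector_model()
  sv_eq <- equivalent_thickness(det$sv_thickness, det$density, pmma$density)
  # crossers: deposited energy over the mean chord length
  for (e in c(6, 7, 8)) {
    y <- as.numeric(alpha_event_lineal_energy(e, det, mode = "physics",
                                              table = pmma))
    de_oracle <- oracle_energy_loss(e, sv_eq, pmma)
    expect_equal(y * det$mean_chord_length / 1000, de_oracle,
                 tolerance = 1e-6)
  }
  # stopper: full energy over its residual range in silicon
  e_stop <- 2.0
  r_si <- equivalent_thickness(interpolate_range(e_stop, pmma),
                               pmma$density, det$density)
  expect_lt(interpolate_range(e_stop, pmma), sv_eq)  # it does stop
  y_stop <- alpha_event_lineal_energy(e_stop, det, mode = "physics",
                                      table = pmma)
  expect_equal(as.numeric(y_stop), 1000 * e_stop / r_si, tolerance = 1e-12)
  # clipping is flagged
  y_clip <- alpha_event_lineal_energy(e_stop, det, mode = "physics",
                                      table = pmma, y_max = 100)
  expect_equal(as.numeric(y_clip), 100)
  expect_equal(attr(y_clip, "clipped"), 1L)
})
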