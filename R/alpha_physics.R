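# Alpha-particle energetics for the p + 11B -> 3-alpha channel: range-energy
# interpolation, material thickness equivalence, separation-gap transmission,
# residual energy after slowing down, and conversion of an alpha reaching the
# sensitive volume into a lineal-energy value.

#' Alpha range--energy table
#'
#' A monotone range--energy relation for alpha particles in a named material,
#' defined by a small set of anchors. Between anchors the range is piecewise
#' linear in energy; outside the anchor domain it is extrapolated with a power
#' law `R = c * E^k` whose exponent is fitted to the two nearest anchors, which
#' matches the physically expected range--energy behaviour far better than
#' linear extension.
#'
#' @param energy_MeV numeric vector of anchor energies (MeV), strictly
#'   increasing.
#' @param range_um numeric vector of anchor ranges (micrometres), strictly
#'   increasing, same length as `energy_MeV`.
#' @param material material name (informational).
#' @param density material density in g/cm^3.
#' @return an object of class `range_table`.
#' @examples
#' tb <- pmma_range_table()
#' interpolate_range(6, tb)   # 45 um anchor
#' invert_range(33, tb)       # 5 MeV anchor
#' @export
range_table <- function(energy_MeV, range_um, material = "PMMA", density = 1.18) {
  if (length(energy_MeV) < 2L || length(energy_MeV) != length(range_um)) {
    stop_domain("need at least two (energy, range) anchors of equal length")
  }
  if (any(diff(energy_MeV) <= 0) || any(diff(range_um) <= 0)) {
    stop_domain("anchors must be strictly increasing in both energy and range")
  }
  if (any(energy_MeV <= 0) || any(range_um <= 0)) {
    stop_domain("anchor energies and ranges must be positive")
  }
  check_positive(density, "density")
  # power-law exponents k = dlog(R)/dlog(E) at each end, for extrapolation
  n <- length(energy_MeV)
  k_lo <- log(range_um[2] / range_um[1]) / log(energy_MeV[2] / energy_MeV[1])
  k_hi <- log(range_um[n] / range_um[n - 1]) / log(energy_MeV[n] / energy_MeV[n - 1])
  structure(
    list(
      energy = as.numeric(energy_MeV), range = as.numeric(range_um),
      material = material, density = density,
      k_lo = k_lo, c_lo = range_um[1] / energy_MeV[1]^k_lo,
      k_hi = k_hi, c_hi = range_um[n] / energy_MeV[n]^k_hi
    ),
    class = "range_table"
  )
}

#' @export
print.range_table <- function(x, ...) {
  cat(sprintf(
    "<range_table> %s (density %.3g g/cm^3), %d anchors %.3g-%.3g MeV\n",
    x$material, x$density, length(x$energy), min(x$energy), max(x$energy)
  ))
  invisible(x)
}

#' Alpha range--energy anchors in PMMA
#'
#' The default stopping-range table used throughout: alpha ranges in PMMA of
#' 33, 45, 58 and 73 micrometres at 5, 6, 7 and 8 MeV (density 1.18 g/cm^3).
#'
#' @return a [range_table].
#' @export
pmma_range_table <- function() {
  range_table(c(5, 6, 7, 8), c(33, 45, 58, 73), material = "PMMA", density = 1.18)
}

#' Interpolate alpha range at a given energy
#'
#' Piecewise-linear inside the anchor domain, power-law extrapolation outside.
#'
#' @param energy energy in MeV (vectorised), must be positive.
#' @param table a [range_table].
#' @return range in micrometres.
#' @export
interpolate_range <- function(energy, table) {
  stopifnot(inherits(table, "range_table"))
  if (length(energy) == 0L) return(numeric(0))
  if (any(!is.finite(energy)) || any(energy <= 0)) {
    stop_domain("`energy` must be positive and finite")
  }
  r <- numeric(length(energy))
  lo <- energy < table$energy[1]
  hi <- energy > table$energy[length(table$energy)]
  mid <- !lo & !hi
  if (any(mid)) {
    r[mid] <- stats::approx(table$energy, table$range, xout = energy[mid])$y
  }
  if (any(lo)) r[lo] <- table$c_lo * energy[lo]^table$k_lo
  if (any(hi)) r[hi] <- table$c_hi * energy[hi]^table$k_hi
  r
}

#' Invert the range--energy relation
#'
#' Exact monotone inverse of [interpolate_range()]: returns the energy whose
#' range equals the given value.
#'
#' @param range range in micrometres (vectorised), must be positive.
#' @param table a [range_table].
#' @return energy in MeV.
#' @export
invert_range <- function(range, table) {
  stopifnot(inherits(table, "range_table"))
  if (length(range) == 0L) return(numeric(0))
  if (any(!is.finite(range)) || any(range <= 0)) {
    stop_domain("`range` must be positive and finite")
  }
  e <- numeric(length(range))
  n <- length(table$range)
  lo <- range < table$range[1]
  hi <- range > table$range[n]
  mid <- !lo & !hi
  if (any(mid)) {
    e[mid] <- stats::approx(table$range, table$energy, xout = range[mid])$y
  }
  if (any(lo)) e[lo] <- (range[lo] / table$c_lo)^(1 / table$k_lo)
  if (any(hi)) e[hi] <- (range[hi] / table$c_hi)^(1 / table$k_hi)
  e
}

#' Mass-thickness equivalent of a layer in another material
#'
#' Converts a physical thickness between materials by conserving areal mass:
#' `t' = t * rho_from / rho_to`. This is the standard equivalence used to
#' express, e.g., a 40 um low-density polyethylene window (0.92 g/cm^3) as
#' about 31 um of PMMA or 37 um of water.
#'
#' @param thickness layer thickness in micrometres.
#' @param density_from density of the layer material, g/cm^3.
#' @param density_to density of the target material, g/cm^3.
#' @return equivalent thickness in micrometres of the target material.
#' @export
equivalent_thickness <- function(thickness, density_from, density_to) {
  if (any(thickness <= 0)) stop_domain("`thickness` must be positive")
  check_positive(density_from, "density_from")
  check_positive(density_to, "density_to")
  thickness * density_from / density_to
}

#' Alpha-energy spectrum model for the three-alpha breakup
#'
#' Parametric model of the alpha-particle energy distribution produced by the
#' p + 11B -> 3-alpha reaction, bounded above by the spectral endpoint (the
#' reaction Q-value, 8.68 MeV, by default).
#'
#' Kinds: `"uniform"` — flat on (0, e_max], the deliberately broad,
#' assumption-light default; `"three_body"` — three-body phase-space shape
#' `dN/dE ~ sqrt(E) * sqrt(e_max - E)`; `"custom_tabulated"` — user-supplied
#' `(energy, weight)` grid, linearly interpolated as a density.
#'
#' @param kind one of `"uniform"`, `"three_body"`, `"custom_tabulated"`.
#' @param e_max spectral endpoint in MeV (default 8.68, the reaction Q-value).
#' @param weight admixture fraction in `[0, 1]`: the probability that an event
#'   in a mixed proton/alpha stream is alpha-induced (before gap filtering).
#' @param tab for `"custom_tabulated"`, a data frame with columns `energy` and
#'   `weight`.
#' @return an object of class `alpha_spectrum_model`.
#' @export
alpha_spectrum_model <- function(kind = c("uniform", "three_body", "custom_tabulated"),
                                 e_max = 8.68, weight = 0, tab = NULL) {
  kind <- match.arg(kind)
  check_positive(e_max, "e_max")
  if (!is.numeric(weight) || length(weight) != 1L || weight < 0 || weight > 1) {
    stop_domain("`weight` must be a single number in [0, 1]")
  }
  if (kind == "custom_tabulated") {
    if (is.null(tab) || !all(c("energy", "weight") %in% names(tab))) {
      stop_domain("custom_tabulated requires `tab` with columns energy, weight")
    }
    if (any(tab$energy <= 0) || any(tab$energy > e_max) || any(tab$weight < 0)) {
      stop_domain("tabulated energies must lie in (0, e_max] with non-negative weights")
    }
  }
  structure(list(kind = kind, e_max = e_max, weight = weight, tab = tab),
            class = "alpha_spectrum_model")
}

# Unnormalised spectral density of an alpha_spectrum_model on (0, e_max].
alpha_density <- function(model, e) {
  out <- numeric(length(e))
  inside <- e > 0 & e <= model$e_max
  out[inside] <- switch(model$kind,
    uniform = 1,
    three_body = sqrt(e[inside]) * sqrt(model$e_max - e[inside]),
    custom_tabulated = stats::approx(model$tab$energy, model$tab$weight,
                                     xout = e[inside], rule = 2)$y
  )
  out
}

#' Sample alpha energies from a spectrum model
#'
#' @param model an [alpha_spectrum_model].
#' @param n number of samples (non-negative).
#' @param seed integer seed; fixed seed gives identical samples.
#' @return numeric vector of `n` energies in MeV, all in `(0, e_max]`.
#' @export
sample_alpha_energies <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "alpha_spectrum_model"))
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n)) {
    stop_domain("`n` must be a single non-negative integer")
  }
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))
  with_seed(seed, r_alpha(model, n))
}

# Draw n alpha energies using the current RNG state (no seeding); the
# building block shared by sample_alpha_energies() and the event generators.
r_alpha <- function(model, n) {
  if (n == 0L) return(numeric(0))
  if (model$kind == "uniform") {
    stats::runif(n, 0, model$e_max)
  } else if (model$kind == "three_body") {
    # E = e_max * X with X ~ Beta(3/2, 3/2) reproduces sqrt(E)*sqrt(e_max - E)
    model$e_max * stats::rbeta(n, 1.5, 1.5)
  } else {
    # inverse-CDF sampling on a fine grid of the tabulated density
    grid <- seq(1e-9, model$e_max, length.out = 4096L)
    dens <- alpha_density(model, grid)
    cdf <- cumsum(dens)
    cdf <- cdf / cdf[length(cdf)]
    keep <- !duplicated(cdf)
    stats::approx(cdf[keep], grid[keep], xout = stats::runif(n), rule = 2)$y
  }
}

#' Separation-gap geometry between the boron volume and the sensitive volume
#'
#' @param gap_thickness physical gap thickness in micrometres (in `material`).
#' @param material name of the gap material.
#' @param density gap material density, g/cm^3.
#' @param window_layers optional data frame of extra window layers with columns
#'   `thickness` (um) and `density` (g/cm^3), e.g. a thin plastic foil window.
#' @return an object of class `gap_geometry`.
#' @export
gap_geometry <- function(gap_thickness, material = "PMMA", density = 1.18,
                         window_layers = NULL) {
  check_nonneg(gap_thickness, "gap_thickness")
  check_positive(density, "density")
  if (!is.null(window_layers)) {
    if (!all(c("thickness", "density") %in% names(window_layers))) {
      stop_domain("`window_layers` needs columns thickness and density")
    }
    if (any(window_layers$thickness < 0) || any(window_layers$density <= 0)) {
      stop_domain("window layer thicknesses must be >= 0 and densities > 0")
    }
  }
  structure(list(gap_thickness = gap_thickness, material = material,
                 density = density, window_layers = window_layers),
            class = "gap_geometry")
}

# Total barrier thickness expressed in the range table's material (um),
# combining the gap proper and any window layers by mass-thickness scaling.
effective_gap <- function(gap, table) {
  stopifnot(inherits(gap, "gap_geometry"), inherits(table, "range_table"))
  total <- if (gap$gap_thickness > 0) {
    equivalent_thickness(gap$gap_thickness, gap$density, table$density)
  } else 0
  if (!is.null(gap$window_layers)) {
    wl <- gap$window_layers
    pos <- wl$thickness > 0
    if (any(pos)) {
      total <- total + sum(equivalent_thickness(wl$thickness[pos],
                                                wl$density[pos], table$density))
    }
  }
  total
}

#' Fraction of alpha particles that traverse the separation gap
#'
#' Probability that an alpha drawn from the spectrum has enough range to cross
#' the barrier (gap plus window layers, mass-thickness scaled to the range
#' table's material). Closed-form for the uniform spectrum; numerical
#' integration of the spectral density otherwise. Monotone non-increasing in
#' gap thickness: 1 at zero gap, 0 once the gap exceeds the endpoint range.
#'
#' @param model an [alpha_spectrum_model].
#' @param gap a [gap_geometry].
#' @param table a [range_table].
#' @return transmission fraction in `[0, 1]`.
#' @export
transmission_fraction <- function(model, gap, table) {
  stopifnot(inherits(model, "alpha_spectrum_model"))
  g <- effective_gap(gap, table)
  if (g <= 0) return(1)
  if (g >= interpolate_range(model$e_max, table)) return(0)
  e_thr <- invert_range(g, table)
  if (e_thr <= 0) return(1)
  if (model$kind == "uniform") {
    max(0, min(1, (model$e_max - e_thr) / model$e_max))
  } else {
    num <- stats::integrate(function(e) alpha_density(model, e),
                            e_thr, model$e_max, rel.tol = 1e-8)$value
    den <- stats::integrate(function(e) alpha_density(model, e),
                            0, model$e_max, rel.tol = 1e-8)$value
    max(0, min(1, num / den))
  }
}

#' Residual alpha energy after crossing the gap
#'
#' Range-based slowing down: the residual range after the barrier is
#' `R(E_in) - gap`, and the residual energy is its inverse image under the
#' range table. Alphas whose range is exhausted inside the barrier are
#' reported as absorbed (`NA`).
#'
#' @param energy_in incident energy in MeV (vectorised).
#' @param gap a [gap_geometry].
#' @param table a [range_table].
#' @return residual energies in MeV; `NA` where the alpha is absorbed.
#' @export
residual_energy <- function(energy_in, gap, table) {
  if (any(!is.finite(energy_in)) || any(energy_in <= 0)) {
    stop_domain("`energy_in` must be positive")
  }
  g <- effective_gap(gap, table)
  r_res <- interpolate_range(energy_in, table) - g
  out <- rep(NA_real_, length(energy_in))
  ok <- r_res > 0
  if (any(ok)) out[ok] <- invert_range(r_res[ok], table)
  out
}

#' Detector geometry and acquisition constants
#'
#' Describes the single-sensitive-volume SOI microdosimeter: a thin silicon
#' sensitive layer of small area read out through an oscilloscope.
#'
#' @param sv_thickness sensitive-volume thickness in micrometres (default 10).
#' @param sv_area sensitive-volume area in square micrometres (default 2500).
#' @param mean_chord_length mean chord length in micrometres; defaults to the
#'   thickness (normal-incidence convention).
#' @param oscilloscope_full_scale full-scale oscilloscope range in mV
#'   (default 500).
#' @param sample_interval acquisition sample interval, arbitrary time units.
#' @param density silicon density in g/cm^3 (default 2.33), used when scaling
#'   range tables into the detector material.
#' @return an object of class `detector_model`.
#' @export
detector_model <- function(sv_thickness = 10, sv_area = 2500,
                           mean_chord_length = sv_thickness,
                           oscilloscope_full_scale = 500,
                           sample_interval = 1, density = 2.33) {
  check_positive(sv_thickness, "sv_thickness")
  check_positive(sv_area, "sv_area")
  check_positive(mean_chord_length, "mean_chord_length")
  check_positive(oscilloscope_full_scale, "oscilloscope_full_scale")
  check_positive(sample_interval, "sample_interval")
  check_positive(density, "density")
  if (mean_chord_length > sv_thickness) {
    stop_domain("mean_chord_length must not exceed sv_thickness (normal incidence)")
  }
  structure(list(sv_thickness = sv_thickness, sv_area = sv_area,
                 mean_chord_length = mean_chord_length,
                 oscilloscope_full_scale = oscilloscope_full_scale,
                 sample_interval = sample_interval, density = density),
            class = "detector_model")
}

#' Lineal energy of an alpha event in the sensitive volume
#'
#' Converts the energy of an alpha particle arriving at the sensitive volume
#' into a lineal-energy value, in keV/um.
#'
#' Two modes:
#' \describe{
#'   \item{`"empirical"` (default)}{a draw from a bounded uniform distribution
#'     over `[y_lo, y_hi]` keV/um (defaults 8--20), representing the
#'     high-lineal-energy tail where the boron-induced excess is observed,
#'     without committing to a detector-response model.}
#'   \item{`"physics"`}{deterministic slowing-down: the range table is scaled
#'     into the detector material by mass thickness; a crosser deposits
#'     `E_in - E_out` over the mean chord length, a stopper deposits its full
#'     energy over its residual range. Values above `y_max` are clipped and
#'     counted in the `"clipped"` attribute.}
#' }
#'
#' @param energy_at_sv alpha energies at the sensitive volume, MeV (vectorised).
#' @param detector a [detector_model].
#' @param mode `"empirical"` or `"physics"`.
#' @param table a [range_table] (physics mode; material scaled to silicon).
#' @param y_lo,y_hi empirical-mode bounds in keV/um.
#' @param y_max physics-mode clipping ceiling in keV/um (default `Inf`).
#' @param seed integer seed for the empirical draw.
#' @return numeric vector of lineal energies (keV/um); physics mode carries a
#'   `"clipped"` attribute with the number of clipped values.
#' @export
alpha_event_lineal_energy <- function(energy_at_sv, detector = detector_model(),
                                      mode = c("empirical", "physics"),
                                      table = pmma_range_table(),
                                      y_lo = 8, y_hi = 20, y_max = Inf,
                                      seed = 1L) {
  mode <- match.arg(mode)
  if (length(energy_at_sv) == 0L) return(numeric(0))
  if (any(!is.finite(energy_at_sv)) || any(energy_at_sv <= 0)) {
    stop_domain("`energy_at_sv` must be positive")
  }
  if (mode == "empirical") {
    if (!is.finite(y_lo) || !is.finite(y_hi) || y_lo <= 0 || y_hi <= y_lo) {
      stop_domain("empirical mode needs 0 < y_lo < y_hi")
    }
    return(with_seed(seed, stats::runif(length(energy_at_sv), y_lo, y_hi)))
  }
  # physics mode: express the silicon sensitive layer as a thickness in the
  # range table's material (mass-thickness scaling), then slow down across it
  sv_eq <- equivalent_thickness(detector$sv_thickness, detector$density,
                                table$density)
  r_in <- interpolate_range(energy_at_sv, table)
  crosser <- r_in > sv_eq
  y <- numeric(length(energy_at_sv))
  if (any(crosser)) {
    e_out <- invert_range(r_in[crosser] - sv_eq, table)
    # 1000 * MeV / um = keV/um
    y[crosser] <- 1000 * (energy_at_sv[crosser] - e_out) / detector$mean_chord_length
  }
  if (any(!crosser)) {
    # stopper: full energy over the track length actually travelled (silicon)
    r_si <- equivalent_thickness(r_in[!crosser], table$density, detector$density)
    y[!crosser] <- 1000 * energy_at_sv[!crosser] / r_si
  }
  clipped <- sum(y > y_max)
  y[y > y_max] <- y_max
  attr(y, "clipped") <- clipped
  y
}
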