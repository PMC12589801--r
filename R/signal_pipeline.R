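# The measurement chain: noise-threshold determination from pre-irradiation
# traces, peak extraction, linear calibration against a reference spectrum,
# conversion of peak amplitudes to lineal energy, 0.5 keV/um binning, and
# Monte Carlo propagation of calibration uncertainty to the dose-averaged
# lineal energy.

#' Event list
#'
#' A flat list of per-event values — either oscilloscope peak amplitudes (mV)
#' or lineal energies (keV/um) — together with bookkeeping counts for
#' saturated and dropped events.
#'
#' @param values numeric vector of non-negative event values.
#' @param unit `"mV"` or `"keV/um"`.
#' @param saturated_count number of events at the oscilloscope full scale.
#' @param dropped_count number of events removed (e.g. non-positive after
#'   calibration).
#' @return an object of class `event_list`.
#' @export
event_list <- function(values, unit = c("mV", "keV/um"),
                       saturated_count = 0L, dropped_count = 0L) {
  unit <- match.arg(unit)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop_domain("event values must be finite and non-negative")
  }
  structure(list(values = as.numeric(values), unit = unit,
                 saturated_count = as.integer(saturated_count),
                 dropped_count = as.integer(dropped_count)),
            class = "event_list")
}

#' @export
print.event_list <- function(x, ...) {
  cat(sprintf("<event_list> %d events [%s], %d saturated, %d dropped\n",
              length(x$values), x$unit, x$saturated_count, x$dropped_count))
  invisible(x)
}

#' @export
length.event_list <- function(x) length(x$values)

#' Oscilloscope trace
#'
#' @param samples numeric vector of voltages in mV (non-empty).
#' @param sample_interval time per sample, arbitrary units.
#' @param metadata optional named list of condition identifiers.
#' @return an object of class `trace`.
#' @export
osc_trace <- function(samples, sample_interval = 1, metadata = list()) {
  if (length(samples) == 0L || any(!is.finite(samples))) {
    stop_domain("`samples` must be non-empty and finite")
  }
  check_positive(sample_interval, "sample_interval")
  structure(list(samples = as.numeric(samples),
                 sample_interval = sample_interval, metadata = metadata),
            class = "trace")
}

#' Linear calibration model
#'
#' The linear conversion from oscilloscope peak amplitude to lineal energy,
#' `y = a * P + b`, with one-sigma uncertainties on both coefficients.
#'
#' @param a slope in keV/um per mV, `> 0`.
#' @param b intercept in keV/um.
#' @param u_a one-sigma uncertainty of `a` (same units as `a`).
#' @param u_b one-sigma uncertainty of `b` (keV/um).
#' @param fit_diagnostics optional list of fit residual summaries.
#' @return an object of class `calibration_model`.
#' @export
calibration_model <- function(a, b = 0, u_a = 0, u_b = 0,
                              fit_diagnostics = NULL) {
  check_positive(a, "a")
  check_nonneg(u_a, "u_a")
  check_nonneg(u_b, "u_b")
  structure(list(a = a, b = b, u_a = u_a, u_b = u_b,
                 fit_diagnostics = fit_diagnostics),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> y = %.5g * P + %.5g  (u_a = %.3g [%.2g%%], u_b = %.3g)\n",
              x$a, x$b, x$u_a, 100 * x$u_a / x$a, x$u_b))
  invisible(x)
}

#' Noise threshold from a pre-irradiation baseline trace
#'
#' `threshold = mean(baseline) + k * sd(baseline)`; only pulses above this are
#' treated as beam-induced events.
#'
#' @param baseline a [trace] recorded without beam.
#' @param k standard-deviation multiplier (default 5).
#' @return threshold in mV.
#' @export
determine_threshold <- function(baseline, k = 5) {
  stopifnot(inherits(baseline, "trace"))
  check_nonneg(k, "k")
  s <- stats::sd(baseline$samples)
  if (is.na(s)) s <- 0  # single-sample baseline
  mean(baseline$samples) + k * s
}

#' Extract pulse peaks from a trace
#'
#' Finds local maxima strictly above the threshold, keeping only the largest
#' peak within any window of `min_separation` samples (greedy, highest
#' amplitude wins). Samples at or above the full-scale voltage are recorded as
#' saturated.
#'
#' @param tr a [trace].
#' @param threshold detection threshold in mV (`>= 0`).
#' @param min_separation minimum sample distance between accepted peaks.
#' @param full_scale oscilloscope full-scale voltage in mV (default 500).
#' @return an [event_list] of peak amplitudes in mV.
#' @export
extract_peaks <- function(tr, threshold, min_separation = 10, full_scale = 500) {
  stopifnot(inherits(tr, "trace"))
  check_nonneg(threshold, "threshold")
  v <- tr$samples
  n <- length(v)
  if (n < 3L) return(event_list(numeric(0), "mV"))
  # local maxima above threshold; a flat-topped pulse counts once, at the
  # first sample of its plateau
  left <- c(-Inf, v[-n])
  right <- c(v[-1], -Inf)
  cand <- which(v > threshold & v > left & v >= right)
  if (length(cand) == 0L) return(event_list(numeric(0), "mV"))
  # greedy selection by descending amplitude under the separation constraint
  ord <- cand[order(-v[cand], cand)]
  accepted <- integer(0)
  for (i in ord) {
    if (all(abs(accepted - i) >= min_separation)) accepted <- c(accepted, i)
  }
  accepted <- sort(accepted)
  peaks <- v[accepted]
  event_list(peaks, "mV", saturated_count = sum(peaks >= full_scale))
}

#' Fit the linear calibration by quantile matching
#'
#' Determines the coefficients of `y = a * P + b` by regressing reference
#' lineal-energy quantiles on the empirical quantiles of the measured peak
#' amplitudes (quantile--quantile least squares). The default quantile grid is
#' 5% to 95% in 5% steps; tails are excluded to keep the fit robust to
#' thresholding and saturation. Standard errors of the regression coefficients
#' are reported as the calibration uncertainties.
#'
#' @param peaks an [event_list] of peak amplitudes in mV.
#' @param reference a [spectrum_model] describing the expected lineal-energy
#'   distribution at the calibration depth.
#' @param probs quantile grid used for the fit.
#' @return a [calibration_model].
#' @export
fit_calibration <- function(peaks, reference,
                            probs = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(inherits(peaks, "event_list"), inherits(reference, "spectrum_model"))
  if (peaks$unit != "mV") stop_domain("`peaks` must be in mV")
  if (length(peaks$values) < 2L) stop_domain("need at least 2 peak events")
  p_q <- stats::quantile(peaks$values, probs = probs, names = FALSE, type = 7)
  if (stats::sd(p_q) == 0) stop_domain("degenerate peak distribution: zero spread")
  y_q <- reference$q(probs)
  fit <- stats::lm(y_q ~ p_q)
  co <- summary(fit)$coefficients
  calibration_model(
    a = co["p_q", "Estimate"], b = co["(Intercept)", "Estimate"],
    u_a = co["p_q", "Std. Error"], u_b = co["(Intercept)", "Std. Error"],
    fit_diagnostics = list(
      n_events = length(peaks$values), probs = probs,
      residual_sd = stats::sd(stats::residuals(fit)),
      r_squared = summary(fit)$r.squared
    )
  )
}

#' Convert peak amplitudes to lineal energies
#'
#' Applies `y = a * P + b` per event. Non-positive results (sub-threshold
#' artifacts of the affine map) are dropped and counted.
#'
#' @param peaks an [event_list] in mV.
#' @param calib a [calibration_model].
#' @return an [event_list] in keV/um.
#' @export
convert_to_lineal <- function(peaks, calib) {
  stopifnot(inherits(peaks, "event_list"), inherits(calib, "calibration_model"))
  if (peaks$unit != "mV") stop_domain("`peaks` must be in mV")
  y <- calib$a * peaks$values + calib$b
  keep <- y > 0
  event_list(y[keep], "keV/um",
             saturated_count = peaks$saturated_count,
             dropped_count = peaks$dropped_count + sum(!keep))
}

#' Bin lineal energies into the standard spectrum
#'
#' Histograms events into half-open bins `[low, high)` of width 0.5 keV/um
#' over 0--20 keV/um (40 bins). Events at or above 20 keV/um are counted as
#' overflow and their raw values retained so that dose-averaged statistics can
#' still use them. Counts are conserved: `sum(counts) + overflow == n`.
#'
#' @param events an [event_list] in keV/um (or a bare numeric vector).
#' @param bin_width bin width in keV/um (default 0.5).
#' @param y_range spectrum range in keV/um (default `c(0, 20)`).
#' @return an object of class `lineal_spectrum` with fields `bin_edges`,
#'   `counts`, `overflow_count`, `overflow_values`, `n`.
#' @export
bin_spectrum <- function(events, bin_width = 0.5, y_range = c(0, 20)) {
  y <- if (inherits(events, "event_list")) {
    if (events$unit != "keV/um") stop_domain("`events` must be in keV/um")
    events$values
  } else as.numeric(events)
  if (any(y < 0)) stop_domain("lineal energies must be non-negative")
  check_positive(bin_width, "bin_width")
  edges <- seq(y_range[1], y_range[2], by = bin_width)
  over <- y >= y_range[2]
  idx <- findInterval(y[!over], edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(list(bin_edges = edges, counts = counts,
                 overflow_count = sum(over), overflow_values = y[over],
                 n = length(y)),
            class = "lineal_spectrum")
}

#' @export
print.lineal_spectrum <- function(x, ...) {
  cat(sprintf("<lineal_spectrum> %d events in %d bins of %.3g keV/um (%.3g-%.3g), %d overflow\n",
              x$n, length(x$counts), diff(x$bin_edges[1:2]),
              min(x$bin_edges), max(x$bin_edges), x$overflow_count))
  invisible(x)
}

#' Spectrum as a tidy table
#'
#' @param x a `lineal_spectrum`.
#' @param ... unused.
#' @return a tibble with `bin_low_keV_um`, `bin_high_keV_um`, `count`,
#'   including a final overflow row with `bin_high_keV_um = Inf`.
#' @export
as_tibble_spectrum <- function(x, ...) {
  stopifnot(inherits(x, "lineal_spectrum"))
  nb <- length(x$counts)
  tibble::tibble(
    bin_low_keV_um = c(x$bin_edges[-(nb + 1)], x$bin_edges[nb + 1]),
    bin_high_keV_um = c(x$bin_edges[-1], Inf),
    count = c(x$counts, x$overflow_count)
  )
}

#' Propagate calibration uncertainty to the dose-averaged lineal energy
#'
#' Monte Carlo: draws `(a, b)` from independent normals centred on the fitted
#' coefficients with their one-sigma uncertainties, reconverts the peak list
#' and recomputes the dose-averaged lineal energy for each draw, and reports
#' the relative one-sigma spread (SD over mean) of the results.
#'
#' @param calib a [calibration_model] with `u_a`, `u_b` set.
#' @param peaks an [event_list] of peak amplitudes in mV.
#' @param n_mc number of Monte Carlo draws (at least 100; default 2000).
#' @param seed integer seed.
#' @return a list with `relative_sd` (dimensionless 1-sigma of the
#'   dose-averaged lineal energy), `mean_ydbar` (keV/um), and `n_mc`.
#' @export
propagate_calibration_uncertainty <- function(calib, peaks, n_mc = 2000,
                                              seed = 1L) {
  stopifnot(inherits(calib, "calibration_model"),
            inherits(peaks, "event_list"))
  if (n_mc < 100) stop_domain("`n_mc` must be at least 100")
  if (calib$u_a == 0 && calib$u_b == 0) {
    y <- calib$a * peaks$values + calib$b
    return(list(relative_sd = 0, mean_ydbar = ydbar(y[y > 0]), n_mc = 0L))
  }
  P <- peaks$values
  draws <- with_seed(seed, {
    a_i <- stats::rnorm(n_mc, calib$a, calib$u_a)
    # non-positive slopes are unphysical; redraw the rare offenders
    while (any(a_i <= 0)) {
      a_i[a_i <= 0] <- stats::rnorm(sum(a_i <= 0), calib$a, calib$u_a)
    }
    b_i <- stats::rnorm(n_mc, calib$b, calib$u_b)
    vapply(seq_len(n_mc), function(i) {
      y <- a_i[i] * P + b_i[i]
      y <- y[y > 0]
      sum(y^2) / sum(y)
    }, numeric(1))
  })
  list(relative_sd = stats::sd(draws) / mean(draws),
       mean_ydbar = mean(draws), n_mc = as.integer(n_mc))
}
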