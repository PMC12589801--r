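# Microdosimetric statistics: frequency-mean and dose-averaged lineal energy,
# the dose-weighted distribution d(y), repeat aggregation, and the Welch
# comparison used for the boron studies.

# Pull a numeric lineal-energy vector out of the accepted input types.
lineal_values <- function(input) {
  if (inherits(input, "event_list")) {
    if (input$unit != "keV/um") stop_domain("event list must be in keV/um")
    input$values
  } else if (is.numeric(input)) {
    as.numeric(input)
  } else {
    NULL
  }
}

#' Dose-averaged lineal energy
#'
#' Computes the dose-weighted mean lineal energy
#' `sum(y^2 f(y)) / sum(y f(y))`, the study's primary radiation-quality
#' metric. Operates on unbinned event lists (exact) or on a binned
#' [bin_spectrum()] result, in which case bin centres are used and overflow
#' events contribute at their retained raw values (or at the top edge, with a
#' warning, if the raw values were discarded).
#'
#' @param input an [event_list] in keV/um, a bare numeric vector of lineal
#'   energies, or a `lineal_spectrum`.
#' @return dose-averaged lineal energy in keV/um.
#' @export
ydbar <- function(input) {
  y <- lineal_values(input)
  if (!is.null(y)) {
    y <- y[y > 0]
    if (length(y) == 0L) stop_domain("need at least one positive lineal energy")
    return(sum(y^2) / sum(y))
  }
  stopifnot(inherits(input, "lineal_spectrum"))
  m <- spectrum_moments(input)
  if (m$m1 <= 0) stop_domain("empty spectrum")
  m$m2 / m$m1
}

#' Frequency-mean lineal energy
#'
#' `sum(y f(y)) / sum(f(y))` — the unweighted mean, reported alongside the
#' dose average for contrast.
#'
#' @inheritParams ydbar
#' @return frequency-mean lineal energy in keV/um.
#' @export
yfbar <- function(input) {
  y <- lineal_values(input)
  if (!is.null(y)) {
    y <- y[y > 0]
    if (length(y) == 0L) stop_domain("need at least one positive lineal energy")
    return(mean(y))
  }
  stopifnot(inherits(input, "lineal_spectrum"))
  m <- spectrum_moments(input)
  if (m$n == 0) stop_domain("empty spectrum")
  m$m1 / m$n
}

# First and second moment sums of a binned spectrum (bin-centre convention;
# overflow at retained raw values, else at the top edge with a warning).
spectrum_moments <- function(sp) {
  centres <- sp$bin_edges[-length(sp$bin_edges)] + diff(sp$bin_edges) / 2
  m1 <- sum(centres * sp$counts)
  m2 <- sum(centres^2 * sp$counts)
  if (sp$overflow_count > 0) {
    ov <- sp$overflow_values
    if (length(ov) != sp$overflow_count) {
      warning("overflow raw values unavailable; using the top bin edge")
      ov <- rep(max(sp$bin_edges), sp$overflow_count)
    }
    m1 <- m1 + sum(ov)
    m2 <- m2 + sum(ov^2)
  }
  list(m1 = m1, m2 = m2, n = sp$n)
}

#' Dose-weighted distribution d(y)
#'
#' Per-bin dose fractions `d_i = y_i f_i / sum(y_j f_j)`, the standard
#' representation for microdosimetric spectra plots. An overflow row (if any)
#' is carried with a representative lineal energy equal to the dose average of
#' the overflow events, so that `sum(y_i d_i)` reproduces the binned
#' dose-averaged lineal energy exactly.
#'
#' @param spectrum a `lineal_spectrum` from [bin_spectrum()].
#' @return a tibble with `y_mid` (keV/um), `frequency`, `dose_fraction`, and
#'   an `overflow` flag column; `dose_fraction` sums to 1.
#' @export
dose_distribution <- function(spectrum) {
  stopifnot(inherits(spectrum, "lineal_spectrum"))
  if (spectrum$n == 0) stop_domain("empty spectrum")
  centres <- spectrum$bin_edges[-length(spectrum$bin_edges)] +
    diff(spectrum$bin_edges) / 2
  y_mid <- centres
  freq <- spectrum$counts
  dose_mass <- centres * spectrum$counts
  overflow <- rep(FALSE, length(centres))
  if (spectrum$overflow_count > 0) {
    ov <- spectrum$overflow_values
    if (length(ov) != spectrum$overflow_count) {
      ov <- rep(max(spectrum$bin_edges), spectrum$overflow_count)
    }
    y_mid <- c(y_mid, sum(ov^2) / sum(ov))
    freq <- c(freq, spectrum$overflow_count)
    dose_mass <- c(dose_mass, sum(ov))
    overflow <- c(overflow, TRUE)
  }
  total <- sum(dose_mass)
  if (total <= 0) stop_domain("spectrum carries no dose")
  tibble::tibble(y_mid = y_mid, frequency = freq,
                 dose_fraction = dose_mass / total, overflow = overflow)
}

#' Aggregate repeated measurements
#'
#' Sample mean and standard deviation (n - 1 denominator) over repeats of a
#' summary statistic, typically the per-repeat dose-averaged lineal energy.
#'
#' @param values numeric vector of per-repeat values.
#' @return a list with `mean`, `sd` (`NA` with a warning for a single
#'   repeat), and `n`.
#' @export
aggregate_repeats <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop_domain("no repeats supplied")
  if (length(values) == 1L) {
    warning("single repeat: standard deviation undefined")
    return(list(mean = values, sd = NA_real_, n = 1L))
  }
  list(mean = mean(values), sd = stats::sd(values), n = length(values))
}

# Normalise compare_conditions() input to (mean, sd, n), or signal raw data.
as_group_stats <- function(x, name) {
  if (is.numeric(x) && is.null(names(x)) && length(x) >= 2L) {
    return(list(raw = as.numeric(x)))
  }
  if (is.list(x) || (is.numeric(x) && !is.null(names(x)))) {
    x <- as.list(x)
    if (all(c("mean", "sd", "n") %in% names(x))) {
      if (x$n < 2) stop_domain(sprintf("`%s` needs n >= 2", name))
      if (x$sd < 0) stop_domain(sprintf("`%s` needs sd >= 0", name))
      return(list(mean = as.numeric(x$mean), sd = as.numeric(x$sd),
                  n = as.numeric(x$n)))
    }
  }
  stop_domain(sprintf(
    "`%s` must be a numeric vector of repeats (length >= 2) or (mean, sd, n)", name))
}

#' Compare two measurement conditions
#'
#' Two-tailed unpaired t-test between two groups of repeated measurements.
#' Welch's unequal-variance form is the default (the observed group SDs can
#' differ nearly twofold); the pooled-variance Student form is available via
#' `var_equal = TRUE`. Groups may be given either as raw repeat vectors or as
#' `(mean, sd, n)` summary triples, so printed summary rows can be compared
#' without raw data.
#'
#' @param a,b numeric vectors of repeats, or named lists/vectors with
#'   elements `mean`, `sd`, `n`.
#' @param var_equal use the pooled-variance test instead of Welch.
#' @return a list of class `comparison_result`: `mean_a`, `sd_a`, `n_a`,
#'   `mean_b`, `sd_b`, `n_b`, `t_statistic`, `degrees_of_freedom`,
#'   `p_value` (two-tailed), `method`.
#' @export
compare_conditions <- function(a, b, var_equal = FALSE) {
  ga <- as_group_stats(a, "a")
  gb <- as_group_stats(b, "b")
  if (!is.null(ga$raw) && !is.null(gb$raw)) {
    # raw repeats: delegate to the standard test
    both_const <- stats::sd(ga$raw) == 0 && stats::sd(gb$raw) == 0
    if (both_const) {
      ga <- list(mean = mean(ga$raw), sd = 0, n = length(ga$raw))
      gb <- list(mean = mean(gb$raw), sd = 0, n = length(gb$raw))
    } else {
      tt <- stats::t.test(ga$raw, gb$raw, var.equal = var_equal)
      return(structure(list(
        mean_a = mean(ga$raw), sd_a = stats::sd(ga$raw), n_a = length(ga$raw),
        mean_b = mean(gb$raw), sd_b = stats::sd(gb$raw), n_b = length(gb$raw),
        t_statistic = unname(tt$statistic),
        degrees_of_freedom = unname(tt$parameter),
        p_value = tt$p.value,
        method = if (var_equal) "pooled" else "welch"
      ), class = "comparison_result"))
    }
  }
  if (!is.null(ga$raw)) ga <- list(mean = mean(ga$raw), sd = stats::sd(ga$raw), n = length(ga$raw))
  if (!is.null(gb$raw)) gb <- list(mean = mean(gb$raw), sd = stats::sd(gb$raw), n = length(gb$raw))
  va <- ga$sd^2 / ga$n
  vb <- gb$sd^2 / gb$n
  if (va + vb == 0) {
    # degenerate: no variability in either group
    t_stat <- if (ga$mean == gb$mean) 0 else sign(ga$mean - gb$mean) * Inf
    df <- ga$n + gb$n - 2
    p <- if (ga$mean == gb$mean) 1 else 0
  } else if (var_equal) {
    sp2 <- ((ga$n - 1) * ga$sd^2 + (gb$n - 1) * gb$sd^2) / (ga$n + gb$n - 2)
    t_stat <- (ga$mean - gb$mean) / sqrt(sp2 * (1 / ga$n + 1 / gb$n))
    df <- ga$n + gb$n - 2
    p <- 2 * stats::pt(-abs(t_stat), df)
  } else {
    t_stat <- (ga$mean - gb$mean) / sqrt(va + vb)
    # Welch--Satterthwaite effective degrees of freedom
    df <- (va + vb)^2 / (va^2 / (ga$n - 1) + vb^2 / (gb$n - 1))
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  structure(list(
    mean_a = ga$mean, sd_a = ga$sd, n_a = ga$n,
    mean_b = gb$mean, sd_b = gb$sd, n_b = gb$n,
    t_statistic = t_stat, degrees_of_freedom = df, p_value = p,
    method = if (var_equal) "pooled" else "welch"
  ), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "<comparison_result> %s t = %.3f, df = %.2f, p = %.3g\n  a: %.3f +/- %.3f (n=%.0f)   b: %.3f +/- %.3f (n=%.0f)\n",
    x$method, x$t_statistic, x$degrees_of_freedom, x$p_value,
    x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b))
  invisible(x)
}
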