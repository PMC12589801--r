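# Seeded generator of synthetic detector data at three fidelity levels:
# ground-truth lineal-energy event lists, oscilloscope peak-amplitude lists,
# and raw voltage traces, for any (beam energy, depth, boron) condition.

#' Measurement-condition specification
#'
#' Everything needed to generate synthetic data for one experimental
#' condition: the beam, the measurement depth, whether boron is present, the
#' alpha spectrum and gap geometry governing the boron admixture, the
#' generator-side "true" calibration used to turn lineal energies into
#' voltage pulses, and the sampling plan (events per repeat, repeats,
#' repeat-to-repeat jitter, seed).
#'
#' @param beam a [beam_config].
#' @param depth measurement depth, cm water-equivalent.
#' @param boron logical: is the boron-loaded well in place?
#' @param alpha_model an [alpha_spectrum_model]; its `weight` is the
#'   pre-gap-filter probability that an event is alpha-induced.
#' @param gap a [gap_geometry] separating the boron volume from the detector.
#' @param table a [range_table] for alpha slowing-down.
#' @param detector a [detector_model].
#' @param true_calibration a [calibration_model]: the generator's ground-truth
#'   voltage-to-lineal-energy map (defaults give a 20 keV/um event just under
#'   the 500 mV full scale).
#' @param profile a [depth_profile]; defaults to one anchored at the beam's
#'   entrance and Bragg-peak depths.
#' @param family,relative_spread spectral family and coefficient of variation
#'   passed to [reference_spectrum()].
#' @param proton_target optional explicit dose-averaged lineal energy of the
#'   proton component (keV/um), bypassing the profile lookup.
#' @param alpha_y_lo,alpha_y_hi empirical alpha lineal-energy bounds, keV/um.
#' @param alpha_mode `"empirical"` or `"physics"` (see
#'   [alpha_event_lineal_energy()]).
#' @param n_events events per repeat.
#' @param n_repeats number of repeats (default 10).
#' @param repeat_jitter_cv coefficient of variation of the multiplicative
#'   lognormal repeat-to-repeat scale jitter.
#' @param seed integer seed for this condition.
#' @param label optional condition label.
#' @return an object of class `condition_spec`.
#' @export
condition_spec <- function(beam, depth, boron = FALSE,
                           alpha_model = alpha_spectrum_model(weight = 0),
                           gap = gap_geometry(40),
                           table = pmma_range_table(),
                           detector = detector_model(),
                           true_calibration = calibration_model(a = 0.04, b = 0.2),
                           profile = NULL,
                           family = "lognormal", relative_spread = 0.5,
                           proton_target = NULL,
                           alpha_y_lo = 8, alpha_y_hi = 20,
                           alpha_mode = "empirical",
                           n_events = 2000, n_repeats = 10,
                           repeat_jitter_cv = 0.095, seed = 1L,
                           label = NULL) {
  stopifnot(inherits(beam, "beam_config"))
  check_positive(depth, "depth")
  check_positive(n_events, "n_events")
  if (n_repeats < 1) stop_domain("`n_repeats` must be at least 1")
  check_nonneg(repeat_jitter_cv, "repeat_jitter_cv")
  if (is.null(profile)) {
    profile <- depth_profile(entrance_depth = beam$entrance_depth,
                             peak_depth = beam$bragg_peak_depth)
  }
  structure(list(
    beam = beam, depth = depth, boron = isTRUE(boron),
    alpha_model = alpha_model, gap = gap, table = table, detector = detector,
    true_calibration = true_calibration, profile = profile,
    family = family, relative_spread = relative_spread,
    proton_target = proton_target,
    alpha_y_lo = alpha_y_lo, alpha_y_hi = alpha_y_hi, alpha_mode = alpha_mode,
    n_events = as.integer(n_events), n_repeats = as.integer(n_repeats),
    repeat_jitter_cv = repeat_jitter_cv, seed = as.integer(seed),
    label = label
  ), class = "condition_spec")
}

# Proton-component spectrum model for a condition.
proton_spectrum <- function(cond) {
  reference_spectrum(depth = cond$depth, profile = cond$profile,
                     family = cond$family,
                     relative_spread = cond$relative_spread,
                     target = cond$proton_target)
}

# Effective alpha admixture: configured weight times gap transmission,
# zero when the boron flag is off.
effective_alpha_weight <- function(cond) {
  if (!cond$boron || cond$alpha_model$weight == 0) return(0)
  cond$alpha_model$weight *
    transmission_fraction(cond$alpha_model, cond$gap, cond$table)
}

# First/second moments of the alpha lineal-energy component.
alpha_component_moments <- function(cond) {
  if (cond$alpha_mode == "empirical") {
    lo <- cond$alpha_y_lo
    hi <- cond$alpha_y_hi
    list(m1 = (lo + hi) / 2, m2 = (lo^2 + lo * hi + hi^2) / 3)
  } else {
    # physics mode has no closed form: estimate by a large fixed-seed draw
    e <- sample_alpha_energies(cond$alpha_model, 2e5,
                               seed = derive_seed(cond$seed, 777L))
    e_sv <- residual_energy(e, cond$gap, cond$table)
    e_sv <- e_sv[!is.na(e_sv)]
    y <- alpha_event_lineal_energy(e_sv, cond$detector, mode = "physics",
                                   table = cond$table)
    list(m1 = mean(y), m2 = mean(y^2))
  }
}

#' Closed-form ground-truth dose-averaged lineal energy of a condition
#'
#' The mixture dose average from the component moments:
#' `((1 - w) m2_p + w m2_a) / ((1 - w) m1_p + w m1_a)` with `w` the effective
#' (post-gap-transmission) alpha admixture. This is the generator's truth
#' against which the analysis pipeline is validated.
#'
#' @param cond a [condition_spec].
#' @return dose-averaged lineal energy in keV/um.
#' @export
mixture_truth_ydbar <- function(cond) {
  stopifnot(inherits(cond, "condition_spec"))
  ps <- proton_spectrum(cond)
  w <- effective_alpha_weight(cond)
  if (w == 0) return(ps$ydbar)
  am <- alpha_component_moments(cond)
  ((1 - w) * ps$m2 + w * am$m2) / ((1 - w) * ps$m1 + w * am$m1)
}

#' Solve the alpha admixture needed for a target mixture dose average
#'
#' Inverts the mixture moment ratio: finds the effective alpha fraction `w`
#' such that the mixture of a proton component (dose average `ydbar_proton`)
#' and the empirical alpha component on `[y_lo, y_hi]` has dose-averaged
#' lineal energy `target`. Used by the summary-table preset to pin the
#' generator truth to printed condition means, since the per-proton reaction
#' yield at 100 ppm boron is not known.
#'
#' @param target desired mixture dose-averaged lineal energy, keV/um.
#' @param ydbar_proton dose average of the proton component, keV/um.
#' @param relative_spread proton spectral coefficient of variation.
#' @param family proton spectral family.
#' @param y_lo,y_hi empirical alpha bounds, keV/um.
#' @return effective alpha fraction `w` in `[0, 1]`.
#' @export
solve_alpha_weight <- function(target, ydbar_proton, relative_spread = 0.5,
                               family = "lognormal", y_lo = 8, y_hi = 20) {
  ps <- reference_spectrum(target = ydbar_proton, family = family,
                           relative_spread = relative_spread)
  m1a <- (y_lo + y_hi) / 2
  m2a <- (y_lo^2 + y_lo * y_hi + y_hi^2) / 3
  num <- ps$m2 - target * ps$m1
  den <- (ps$m2 - target * ps$m1) - (m2a - target * m1a)
  w <- num / den
  if (!is.finite(w) || w < 0 || w > 1) {
    stop_domain("target dose average unreachable with this alpha component")
  }
  w
}

#' Generate one ground-truth lineal-energy event stream
#'
#' Draws `cond$n_events` single-event lineal energies from the condition's
#' mixture: with probability `1 - w` a proton event from the reference
#' spectrum at the condition depth, with probability `w` an alpha event whose
#' energy is sampled from the alpha spectrum, filtered through the separation
#' gap, and converted to lineal energy. `w` is the configured alpha weight
#' times the gap transmission when boron is present, zero otherwise.
#'
#' @param cond a [condition_spec].
#' @param seed optional seed override (defaults to `cond$seed`).
#' @return an [event_list] in keV/um.
#' @export
generate_event_stream <- function(cond, seed = cond$seed) {
  stopifnot(inherits(cond, "condition_spec"))
  ps <- proton_spectrum(cond)
  w <- effective_alpha_weight(cond)
  n <- cond$n_events
  with_seed(seed, {
    n_alpha <- stats::rbinom(1L, n, w)
    y_p <- if (n - n_alpha > 0) ps$r(n - n_alpha) else numeric(0)
    y_a <- numeric(0)
    if (n_alpha > 0) {
      if (cond$alpha_mode == "empirical") {
        y_a <- stats::runif(n_alpha, cond$alpha_y_lo, cond$alpha_y_hi)
      } else {
        # physics mode: keep sampling alpha energies until n_alpha of them
        # survive the gap, then slow them down through the sensitive volume
        e_sv <- numeric(0)
        while (length(e_sv) < n_alpha) {
          e <- r_alpha(cond$alpha_model, 4L * n_alpha)
          res <- residual_energy(e, cond$gap, cond$table)
          e_sv <- c(e_sv, res[!is.na(res)])
        }
        e_sv <- e_sv[seq_len(n_alpha)]
        r_in <- interpolate_range(e_sv, cond$table)
        sv_eq <- equivalent_thickness(cond$detector$sv_thickness,
                                      cond$detector$density, cond$table$density)
        crosser <- r_in > sv_eq
        y_a <- numeric(n_alpha)
        if (any(crosser)) {
          e_out <- invert_range(r_in[crosser] - sv_eq, cond$table)
          y_a[crosser] <- 1000 * (e_sv[crosser] - e_out) /
            cond$detector$mean_chord_length
        }
        if (any(!crosser)) {
          r_si <- equivalent_thickness(r_in[!crosser], cond$table$density,
                                       cond$detector$density)
          y_a[!crosser] <- 1000 * e_sv[!crosser] / r_si
        }
      }
    }
    y <- sample(c(y_p, y_a))
    event_list(y, "keV/um")
  })
}

#' Generate a raw oscilloscope trace for a condition
#'
#' Gaussian baseline noise plus voltage pulses at Poisson-distributed arrival
#' times. Each pulse is a step rise to its peak followed by a single
#' exponential decay; the peak amplitude inverts the generator's true
#' calibration, `P = (y - b) / a`, for a lineal energy drawn from the
#' condition mixture. Amplitudes beyond the oscilloscope full scale are
#' clipped and counted.
#'
#' @param cond a [condition_spec].
#' @param duration trace length in samples.
#' @param rate expected pulses per sample (Poisson).
#' @param baseline_mean,baseline_sd baseline noise parameters, mV.
#' @param decay_samples pulse exponential decay constant, in samples.
#' @param seed optional seed override.
#' @return a [trace]; attributes `"true_y"` (the underlying lineal energies),
#'   `"pulse_positions"` and `"clipped_count"` support round-trip testing.
#' @export
generate_trace <- function(cond, duration, rate = 0.002,
                           baseline_mean = 2, baseline_sd = 0.5,
                           decay_samples = 5, seed = cond$seed) {
  stopifnot(inherits(cond, "condition_spec"))
  check_positive(duration, "duration")
  check_nonneg(rate, "rate")
  duration <- as.integer(duration)
  if (rate * decay_samples > 0.2) {
    warning("pulse rate implies substantial overlap; pile-up is not modelled")
  }
  calib <- cond$true_calibration
  fs <- cond$detector$oscilloscope_full_scale
  with_seed(seed, {
    v <- stats::rnorm(duration, baseline_mean, baseline_sd)
    n_pulse <- stats::rpois(1L, rate * duration)
    true_y <- numeric(0)
    pos <- integer(0)
    clipped <- 0L
    if (n_pulse > 0) {
      pos <- sort(sample.int(duration, min(n_pulse, duration)))
      stream <- generate_event_stream(
        cond_with_n(cond, length(pos)), seed = derive_seed(seed, 31L))
      true_y <- stream$values
      amp <- (true_y - calib$b) / calib$a
      clipped <- sum(amp > fs)
      amp <- pmin(amp, fs)
      tail_len <- ceiling(decay_samples * 8)
      decay <- exp(-(0:tail_len) / decay_samples)
      for (i in seq_along(pos)) {
        idx <- pos[i]:min(duration, pos[i] + tail_len)
        v[idx] <- v[idx] + amp[i] * decay[seq_along(idx)]
      }
    }
    v <- pmin(pmax(v, -fs), fs)
    out <- osc_trace(v, sample_interval = cond$detector$sample_interval,
                 metadata = list(label = cond$label, depth = cond$depth,
                                 boron = cond$boron))
    attr(out, "true_y") <- true_y
    attr(out, "pulse_positions") <- pos
    attr(out, "clipped_count") <- clipped
    out
  })
}

# Copy of a condition with a different per-repeat event count.
cond_with_n <- function(cond, n) {
  cond$n_events <- as.integer(n)
  cond
}

#' Generate the full repeated-measurement dataset for a list of conditions
#'
#' For each condition, generates `n_repeats` independent event lists. Repeat
#' seeds are derived deterministically from the condition seed (itself
#' derived from `master_seed` when given). Repeat-to-repeat variability is a
#' multiplicative lognormal scale jitter with coefficient of variation
#' `repeat_jitter_cv` applied to each repeat's lineal energies, emulating
#' run-to-run gain and setup drift; the across-repeat SD of the dose-averaged
#' lineal energy is approximately `jitter_cv * mean` and is how the generator
#' is calibrated to printed repeat SDs.
#'
#' @param conditions a list of [condition_spec] objects (a single spec is
#'   promoted to a list).
#' @param master_seed optional integer; when given, per-condition seeds are
#'   derived from it, overriding each condition's own seed.
#' @return a list (class `study_dataset`) with one element per condition:
#'   `condition`, `repeats` (list of [event_list]), `scale_factors`, `seeds`.
#' @export
generate_study_dataset <- function(conditions, master_seed = NULL) {
  if (inherits(conditions, "condition_spec")) conditions <- list(conditions)
  stopifnot(all(vapply(conditions, inherits, logical(1), "condition_spec")))
  out <- vector("list", length(conditions))
  for (ci in seq_along(conditions)) {
    cond <- conditions[[ci]]
    cond_seed <- if (is.null(master_seed)) cond$seed else
      derive_seed(master_seed, ci)
    cv <- cond$repeat_jitter_cv
    s2 <- log(1 + cv^2)
    reps <- vector("list", cond$n_repeats)
    seeds <- integer(cond$n_repeats)
    scales <- numeric(cond$n_repeats)
    for (r in seq_len(cond$n_repeats)) {
      seeds[r] <- derive_seed(cond_seed, r)
      stream <- generate_event_stream(cond, seed = seeds[r])
      scales[r] <- if (cv > 0) {
        with_seed(derive_seed(cond_seed, 1000L + r),
                  stats::rlnorm(1L, -s2 / 2, sqrt(s2)))
      } else 1
      reps[[r]] <- event_list(stream$values * scales[r], "keV/um")
    }
    out[[ci]] <- list(condition = cond, repeats = reps,
                      scale_factors = scales, seeds = seeds)
  }
  structure(out, class = "study_dataset")
}

#' Convert ground-truth lineal energies into oscilloscope peak amplitudes
#'
#' Inverts the generator's true calibration, `P = (y - b) / a`, producing the
#' peak-amplitude fidelity level of the synthetic data. Amplitudes above the
#' oscilloscope full scale are clipped and counted as saturated when
#' `clip = TRUE`.
#'
#' @param events an [event_list] in keV/um.
#' @param calib the generator-side [calibration_model].
#' @param full_scale oscilloscope full scale, mV; `NULL` disables clipping.
#' @param clip clip at full scale (default `FALSE`).
#' @return an [event_list] in mV.
#' @export
events_to_peaks <- function(events, calib, full_scale = 500, clip = FALSE) {
  stopifnot(inherits(events, "event_list"), inherits(calib, "calibration_model"))
  if (events$unit != "keV/um") stop_domain("`events` must be in keV/um")
  P <- (events$values - calib$b) / calib$a
  P[P < 0] <- 0
  sat <- 0L
  if (clip && !is.null(full_scale)) {
    sat <- sum(P > full_scale)
    P <- pmin(P, full_scale)
  }
  event_list(P, "mV", saturated_count = sat)
}
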