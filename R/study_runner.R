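# Orchestrates the two synthetic experiments end to end: the per-beam depth
# scans and the four-condition boron comparison, with per-beam calibration
# fitted once at the entrance depth and transferred to all other depths.

#' Study configuration
#'
#' @param beams list of [beam_config] objects (default: the 70 and 190 MeV
#'   presets).
#' @param depth_grids named list (by energy, e.g. `"70"`) of measurement-depth
#'   vectors, cm water-equivalent, strictly increasing. Defaults mirror the
#'   study plan: 0.5 cm steps refined to 0.1 cm near the 70 MeV peak, 5 cm
#'   steps refined to 0.2 cm near the 190 MeV peak.
#' @param conditions list of [condition_spec]s for the boron comparison
#'   (default: [preset_conditions()] built from `master_seed`).
#' @param n_events events per repeat for the depth scans.
#' @param n_repeats repeats per depth/condition.
#' @param repeat_jitter_cv repeat jitter for the depth scans.
#' @param n_cal_events events used for the entrance calibration fit.
#' @param output_dir directory used by [report()].
#' @param master_seed master seed from which every other seed derives.
#' @return an object of class `study_config`.
#' @export
study_config <- function(beams = list(preset_beam(70), preset_beam(190)),
                         depth_grids = NULL,
                         conditions = NULL,
                         n_events = 2000, n_repeats = 10,
                         repeat_jitter_cv = 0.095,
                         n_cal_events = 20000,
                         output_dir = tempdir(),
                         master_seed = 1L) {
  stopifnot(all(vapply(beams, inherits, logical(1), "beam_config")))
  if (is.null(depth_grids)) {
    depth_grids <- list(
      `70` = c(seq(0.5, 3.0, by = 0.5), seq(3.1, 3.8, by = 0.1)),
      `190` = c(seq(5, 20, by = 5), seq(21.5, 22.5, by = 0.2))
    )
  }
  for (g in depth_grids) {
    if (any(diff(g) <= 0)) stop_domain("depth grids must be strictly increasing")
  }
  if (is.null(conditions)) {
    conditions <- preset_conditions(n_events = n_events, n_repeats = n_repeats,
                                    seed = master_seed)
  }
  structure(list(beams = beams, depth_grids = depth_grids,
                 conditions = conditions, n_events = n_events,
                 n_repeats = n_repeats, repeat_jitter_cv = repeat_jitter_cv,
                 n_cal_events = n_cal_events, output_dir = output_dir,
                 master_seed = as.integer(master_seed)),
            class = "study_config")
}

#' Fit the entrance calibration for a beam inside the synthetic world
#'
#' Generates a large proton-only event stream at the calibration condition,
#' converts it to oscilloscope peak amplitudes through the generator's true
#' calibration, and fits the linear conversion back by quantile matching
#' against the reference spectrum — the synthetic analogue of calibrating
#' measured entrance spectra against simulated ones.
#'
#' @param cond a [condition_spec] at the entrance depth (boron off, or
#'   treated as proton-only).
#' @param n_cal_events number of calibration events.
#' @param seed integer seed.
#' @return a [calibration_model].
#' @export
fit_entrance_calibration <- function(cond, n_cal_events = 20000, seed = 1L) {
  stopifnot(inherits(cond, "condition_spec"))
  cal_cond <- cond
  cal_cond$boron <- FALSE
  cal_cond <- cond_with_n(cal_cond, n_cal_events)
  stream <- generate_event_stream(cal_cond, seed = seed)
  peaks <- events_to_peaks(stream, cond$true_calibration)
  fit_calibration(peaks, proton_spectrum(cal_cond))
}

# Per-repeat pipeline: truth events -> peaks (true calibration) -> lineal
# energies (fitted calibration) -> dose-averaged lineal energy.
pipeline_ydbar <- function(events, true_calib, fitted_calib) {
  peaks <- events_to_peaks(events, true_calib)
  lineal <- convert_to_lineal(peaks, fitted_calib)
  ydbar(lineal)
}

#' Run the depth scans
#'
#' For each beam: fits the calibration once at the entrance depth, then for
#' every depth in the grid generates `n_repeats` event lists, runs the full
#' peak-conversion pipeline with the transferred calibration, and reports the
#' mean and SD of the dose-averaged lineal energy.
#'
#' @param config a [study_config].
#' @return a tibble with `energy_MeV`, `depth_cm`, `ydbar_mean`, `ydbar_sd`,
#'   `n_repeats`; the fitted calibrations are attached as the
#'   `"calibrations"` attribute.
#' @export
run_depth_scan <- function(config) {
  stopifnot(inherits(config, "study_config"))
  rows <- list()
  calibs <- list()
  for (bi in seq_along(config$beams)) {
    beam <- config$beams[[bi]]
    key <- as.character(beam$nominal_energy)
    grid <- config$depth_grids[[key]]
    if (is.null(grid)) stop_domain(sprintf("no depth grid for %s MeV", key))
    base_cond <- condition_spec(
      beam = beam, depth = beam$entrance_depth, boron = FALSE,
      n_events = config$n_events, n_repeats = config$n_repeats,
      repeat_jitter_cv = config$repeat_jitter_cv,
      seed = derive_seed(config$master_seed, 5000L + bi)
    )
    calib <- fit_entrance_calibration(
      base_cond, n_cal_events = config$n_cal_events,
      seed = derive_seed(config$master_seed, 6000L + bi))
    calibs[[key]] <- calib
    for (di in seq_along(grid)) {
      cond <- base_cond
      cond$depth <- grid[di]
      cond$seed <- derive_seed(config$master_seed, 10000L * bi + di)
      ds <- generate_study_dataset(list(cond))
      yd <- vapply(ds[[1]]$repeats, pipeline_ydbar, numeric(1),
                   true_calib = cond$true_calibration, fitted_calib = calib)
      agg <- aggregate_repeats(yd)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        energy_MeV = beam$nominal_energy, depth_cm = grid[di],
        ydbar_mean = agg$mean, ydbar_sd = agg$sd, n_repeats = agg$n)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "calibrations") <- calibs
  out
}

#' Run the boron comparison study
#'
#' Runs the full pipeline over the configured conditions (entrance and Bragg
#' peak, boron on and off, per beam): per-beam calibration fitted once at the
#' entrance depth on a proton-only stream, applied to every condition; repeat
#' dose averages aggregated per condition; and a two-tailed unpaired Welch
#' test comparing boron on/off within each energy/depth cell. Boron-on
#' entrance conditions are generated with zero effective alpha admixture —
#' alphas produced upstream cannot cross the separation gap at entrance
#' energies — which the preset encodes directly.
#'
#' @param config a [study_config].
#' @return a list of class `study_result`: `condition_table`,
#'   `comparison_table`, `repeat_values` (per-condition dose averages),
#'   `calibrations`, `provenance`.
#' @export
run_boron_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  conds <- config$conditions
  energies <- vapply(conds, function(x) x$beam$nominal_energy, numeric(1))
  # one calibration per beam, fitted at its entrance depth (boron off)
  calibs <- list()
  for (en in unique(energies)) {
    idx <- which(energies == en &
                   vapply(conds, function(x) x$depth == x$beam$entrance_depth,
                          logical(1)) &
                   !vapply(conds, `[[`, logical(1), "boron"))
    if (length(idx) == 0L) {
      stop_domain(sprintf("missing entrance boron-off condition for %g MeV", en))
    }
    calibs[[as.character(en)]] <- fit_entrance_calibration(
      conds[[idx[1]]], n_cal_events = config$n_cal_events,
      seed = derive_seed(config$master_seed, 7000L + as.integer(en)))
  }
  dataset <- generate_study_dataset(conds, master_seed = config$master_seed)
  cond_rows <- list()
  repeat_values <- list()
  for (ci in seq_along(dataset)) {
    cond <- dataset[[ci]]$condition
    calib <- calibs[[as.character(cond$beam$nominal_energy)]]
    yd <- vapply(dataset[[ci]]$repeats, pipeline_ydbar, numeric(1),
                 true_calib = cond$true_calibration, fitted_calib = calib)
    agg <- aggregate_repeats(yd)
    at_peak <- cond$depth >= cond$beam$bragg_peak_depth
    cond_rows[[ci]] <- tibble::tibble(
      energy_MeV = cond$beam$nominal_energy,
      depth_label = if (at_peak) sprintf("Bragg Peak (%g)", cond$depth)
                    else sprintf("Entrance (%g)", cond$depth),
      depth_cm = cond$depth,
      boron = cond$boron,
      ydbar_mean = agg$mean, ydbar_sd = agg$sd, n_repeats = agg$n)
    repeat_values[[ci]] <- yd
  }
  condition_table <- do.call(rbind, cond_rows)
  # within-cell boron-on vs boron-off Welch comparisons
  cmp_rows <- list()
  cells <- unique(condition_table[, c("energy_MeV", "depth_cm")])
  for (k in seq_len(nrow(cells))) {
    sel <- condition_table$energy_MeV == cells$energy_MeV[k] &
      condition_table$depth_cm == cells$depth_cm[k]
    i_off <- which(sel & !condition_table$boron)
    i_on <- which(sel & condition_table$boron)
    if (length(i_off) == 1L && length(i_on) == 1L) {
      cmp <- compare_conditions(repeat_values[[i_on]], repeat_values[[i_off]])
      cmp_rows[[length(cmp_rows) + 1L]] <- tibble::tibble(
        energy_MeV = cells$energy_MeV[k], depth_cm = cells$depth_cm[k],
        t_statistic = cmp$t_statistic,
        degrees_of_freedom = cmp$degrees_of_freedom,
        p_value = cmp$p_value)
    }
  }
  structure(list(
    condition_table = condition_table,
    comparison_table = do.call(rbind, cmp_rows),
    repeat_values = repeat_values,
    calibrations = calibs,
    provenance = list(
      master_seed = config$master_seed,
      n_events = config$n_events, n_repeats = config$n_repeats,
      n_cal_events = config$n_cal_events,
      condition_seeds = vapply(seq_along(dataset), function(i)
        derive_seed(config$master_seed, i), integer(1)),
      package_version = as.character(utils::packageVersion("pbctmicro"))
    )
  ), class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result>\n\nCondition summary:\n")
  print(as.data.frame(x$condition_table))
  cat("\nBoron comparisons (Welch, two-tailed):\n")
  print(as.data.frame(x$comparison_table))
  invisible(x)
}

#' Write study outputs to disk
#'
#' Writes the condition table and comparison table as CSV (column layout
#' mirroring the condition summary: energy, depth label, boron, mean, SD) and
#' a JSON summary including provenance. Content is deterministic for a fixed
#' master seed. Optionally saves diagnostic figures when `ggplot2` is
#' available.
#'
#' @param result a `study_result` from [run_boron_study()].
#' @param dir output directory (created if missing).
#' @param depth_scan optional depth-scan tibble from [run_depth_scan()].
#' @param plots also write PDF figures (requires `ggplot2`).
#' @return invisibly, the vector of files written.
#' @export
report <- function(result, dir, depth_scan = NULL, plots = FALSE) {
  stopifnot(inherits(result, "study_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  f1 <- file.path(dir, "condition_table.csv")
  utils::write.csv(as.data.frame(result$condition_table), f1, row.names = FALSE)
  files <- c(files, f1)
  f2 <- file.path(dir, "comparison_table.csv")
  utils::write.csv(as.data.frame(result$comparison_table), f2, row.names = FALSE)
  files <- c(files, f2)
  if (!is.null(depth_scan)) {
    f3 <- file.path(dir, "depth_scan.csv")
    utils::write.csv(as.data.frame(depth_scan), f3, row.names = FALSE)
    files <- c(files, f3)
  }
  f4 <- file.path(dir, "summary.json")
  jsonlite::write_json(list(
    conditions = result$condition_table,
    comparisons = result$comparison_table,
    provenance = result$provenance
  ), f4, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, f4)
  if (plots && requireNamespace("ggplot2", quietly = TRUE)) {
    if (!is.null(depth_scan)) {
      f <- file.path(dir, "depth_scan.pdf")
      ggplot2::ggsave(f, plot_depth_scan(depth_scan), width = 7, height = 4)
      files <- c(files, f)
    }
    f <- file.path(dir, "condition_bars.pdf")
    ggplot2::ggsave(f, plot_condition_bars(result$condition_table),
                    width = 7, height = 4)
    files <- c(files, f)
  }
  invisible(files)
}

#' Depth-scan figure
#'
#' Dose-averaged lineal energy versus depth with repeat-SD error bars,
#' faceted by beam energy.
#'
#' @param depth_scan tibble from [run_depth_scan()].
#' @return a ggplot object.
#' @export
plot_depth_scan <- function(depth_scan) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_domain("ggplot2 is required for plotting")
  }
  ggplot2::ggplot(depth_scan,
                  ggplot2::aes(x = .data$depth_cm, y = .data$ydbar_mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$ydbar_mean - .data$ydbar_sd,
      ymax = .data$ydbar_mean + .data$ydbar_sd), size = 0.3) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~ energy_MeV, scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Depth (cm water-equivalent)",
                  y = expression(bar(y)[D] ~ "(keV/" * mu * "m)")) +
    ggplot2::theme_bw()
}

#' Boron-comparison bar figure
#'
#' Grouped bars of the per-condition dose average with repeat-SD error bars.
#'
#' @param condition_table tibble from [run_boron_study()].
#' @return a ggplot object.
#' @export
plot_condition_bars <- function(condition_table) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_domain("ggplot2 is required for plotting")
  }
  df <- condition_table
  df$boron_lab <- ifelse(df$boron, "With boron", "Without boron")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth_label,
                                   y = .data$ydbar_mean,
                                   fill = .data$boron_lab)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$ydbar_mean - .data$ydbar_sd,
      ymax = .data$ydbar_mean + .data$ydbar_sd),
      position = ggplot2::position_dodge(0.8), width = 0.2) +
    ggplot2::facet_wrap(~ energy_MeV, scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = expression(bar(y)[D] ~ "(keV/" * mu * "m)"),
                  fill = NULL) +
    ggplot2::theme_bw()
}

#' Overlay of two binned lineal-energy spectra
#'
#' Frequency histograms of two conditions on one axis, the layout used to
#' inspect where a boron-on excess sits (typically the high-lineal-energy
#' tail).
#'
#' @param spec_a,spec_b `lineal_spectrum` objects.
#' @param labels length-2 character labels.
#' @return a ggplot object.
#' @export
plot_spectra_overlay <- function(spec_a, spec_b,
                                 labels = c("without boron", "with boron")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_domain("ggplot2 is required for plotting")
  }
  ta <- as_tibble_spectrum(spec_a)
  tb <- as_tibble_spectrum(spec_b)
  ta$condition <- labels[1]
  tb$condition <- labels[2]
  df <- rbind(ta, tb)
  df <- df[is.finite(df$bin_high_keV_um), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_low_keV_um,
                                   y = .data$count,
                                   colour = .data$condition)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = expression("Lineal energy (keV/" * mu * "m)"),
                  y = "Counts", colour = NULL) +
    ggplot2::theme_bw()
}

#' Read a study configuration from YAML
#'
#' Minimal YAML schema: top-level keys `master_seed`, `n_events`,
#' `n_repeats`, `n_cal_events`, optional `beams` (list with
#' `nominal_energy`, `target_fluence`, `entrance_depth`, `bragg_peak_depth`,
#' optional `mu`, `cyclotron_current`, `transmission_efficiency`).
#'
#' @param path YAML file path.
#' @return a [study_config].
#' @export
read_study_config_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop_domain("the yaml package is required to read YAML configs")
  }
  cfg <- yaml::read_yaml(path)
  beams <- if (!is.null(cfg$beams)) {
    lapply(cfg$beams, function(b) do.call(beam_config, b))
  } else list(preset_beam(70), preset_beam(190))
  args <- cfg[intersect(names(cfg),
                        c("n_events", "n_repeats", "n_cal_events",
                          "repeat_jitter_cv", "master_seed", "output_dir"))]
  do.call(study_config, c(list(beams = beams), args))
}
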