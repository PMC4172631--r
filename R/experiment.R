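#' Experiment configuration
#'
#' Bundles every knob of the end-to-end comparison: phantom, geometry and
#' calibration parameters, the dose ladder, reconstruction kernel and the
#' master seed. Defaults reproduce the study conditions at desk scale: a
#' 100 mAs parent scan, targets 80/60/40/20/10 mAs, 100 kV, smooth kernel,
#' 256 x 256 matrix over a 380 mm FOV, ten 50 mm^2 ROIs per tissue.
#'
#' @param source_mas parent tube load (default 100).
#' @param target_mas dose ladder, all strictly below `source_mas`
#'   (default `c(80, 60, 40, 20, 10)`).
#' @param matrix_size grid edge count for phantom and reconstruction.
#' @param fov_mm field of view (mm).
#' @param n_angles projections over 180 degrees.
#' @param n0_per_mas incident counts per bin per mAs.
#' @param sigma_e electronic noise level (counts).
#' @param kernel reconstruction kernel, identical for both arms.
#' @param rois_per_tissue 50 mm^2 ROIs placed per tissue (default 10).
#' @param seed master seed; every random stage derives its stream from it.
#' @param output_dir optional directory for artifacts (NIfTI images, CSV
#'   and JSON report); `NULL` keeps everything in memory.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(source_mas = 100,
                              target_mas = c(80, 60, 40, 20, 10),
                              matrix_size = 256, fov_mm = 380,
                              n_angles = 180, n0_per_mas = 2e3,
                              sigma_e = 15, kernel = "ramp-hann",
                              rois_per_tissue = 10, seed = 1,
                              output_dir = NULL) {
  if (length(target_mas) && any(target_mas >= source_mas)) {
    rlang::abort("all target_mas must be below source_mas")
  }
  structure(list(source_mas = source_mas, target_mas = target_mas,
                 matrix_size = matrix_size, fov_mm = fov_mm,
                 n_angles = n_angles, n0_per_mas = n0_per_mas,
                 sigma_e = sigma_e, kernel = kernel,
                 rois_per_tissue = rois_per_tissue, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "experiment_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the full original-versus-simulated comparison
#'
#' For each target dose the runner produces a directly acquired scan and a
#' scan simulated from the single high-dose parent, reconstructs both arms
#' with identical parameters, measures every ROI, and assembles the
#' discrepancy report: per-tissue/per-dose percent discrepancies of ROI
#' noise and mean HU, Student-t confidence intervals of the paired
#' differences, per-tissue and per-dose paired t-tests, and overall
#' summaries. All randomness derives from `config$seed`; the same seed
#' yields a byte-identical summary.
#'
#' @param config an [experiment_config()].
#' @param verbose print stage progress (default `FALSE`).
#' @return object of class `lodose_report`: a list with tibbles
#'   `measurements` (per ROI), `cells` (tissue x dose x metric),
#'   `by_dose` (pooled paired t-tests), `summary` (per metric), plus
#'   `config`, `images` (reconstructions) and `seed` provenance.
#' @export
run_experiment <- function(config = experiment_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(format(Sys.time(), "%H:%M:%S "),
                                            sprintf(...))
  seeds <- derive_seeds(config$seed, 3 + 2 * length(config$target_mas))
  say("stage phantom")
  sw <- run_stage("phantom", default_swine_phantom(
    seed = config$seed, matrix_size = config$matrix_size,
    fov_mm = config$fov_mm, rois_per_tissue = config$rois_per_tissue))
  geom <- run_stage("geometry", default_geometry(sw$phantom,
                                                 n_angles = config$n_angles))
  pool <- run_stage("calibration",
                    electronic_noise_pool(sigma_e = config$sigma_e,
                                          seed = seeds[1]))
  calib <- calibration_model(config$n0_per_mas, pool)
  say("stage projection")
  p <- run_stage("projection", radon_project(sw$phantom, geom))
  say("stage parent acquisition (%g mAs)", config$source_mas)
  parent <- run_stage("acquisition",
                      acquire_counts(p, config$source_mas, calib,
                                     rng_seed = seeds[2]))
  recon1 <- function(s) reconstruct_image(s, kernel = config$kernel,
                                          matrix_size = config$matrix_size,
                                          fov_mm = config$fov_mm)
  images <- list(parent = run_stage("reconstruction", recon1(parent)))
  meas <- list(run_stage("roi stats", roi_stats(images$parent, sw$rois)))
  for (i in seq_along(config$target_mas)) {
    tm <- config$target_mas[i]
    say("stage dose %g mAs: acquire + simulate + reconstruct", tm)
    acq <- run_stage("acquisition",
                     acquire_counts(p, tm, calib,
                                    rng_seed = seeds[2 + 2 * i - 1]))
    sim <- run_stage("simulation", simulate_low_dose(
      parent, dose_reduction_plan(config$source_mas, tm, pool,
                                  rng_seed = seeds[2 + 2 * i])))
    im_o <- run_stage("reconstruction", recon1(acq))
    im_s <- run_stage("reconstruction", recon1(sim))
    images[[paste0("original_", tm)]] <- im_o
    images[[paste0("simulated_", tm)]] <- im_s
    meas <- c(meas, list(roi_stats(im_o, sw$rois), roi_stats(im_s, sw$rois)))
  }
  say("stage report")
  measurements <- dplyr::bind_rows(meas)
  report <- run_stage("report", build_report(measurements, config))
  report$rois <- sw$rois
  report$images <- images
  if (!is.null(config$output_dir)) {
    run_stage("artifacts", write_report(report, config$output_dir))
  }
  report
}

# Assemble the discrepancy report from per-ROI measurements of both arms.
build_report <- function(measurements, config) {
  long <- measurements |>
    dplyr::filter(.data$provenance %in% c("original", "simulated") &
                    .data$dose_mas %in% config$target_mas) |>
    tidyr::pivot_longer(c("mean_hu", "sd_hu"), names_to = "metric",
                        values_to = "value") |>
    dplyr::mutate(metric = dplyr::recode(.data$metric, mean_hu = "hu",
                                         sd_hu = "noise"))
  paired <- long |>
    tidyr::pivot_wider(id_cols = c("tissue", "roi_id", "dose_mas", "metric"),
                       names_from = "provenance", values_from = "value")
  if (!nrow(paired)) {
    empty_cells <- tibble::tibble(
      tissue = character(), dose_mas = numeric(), metric = character(),
      orig = numeric(), sim = numeric(), pct_discrepancy = numeric(),
      mean_diff = numeric(), ci_low = numeric(), ci_high = numeric(),
      n = integer(), t = numeric(), p = numeric())
    return(structure(
      list(measurements = measurements, cells = empty_cells,
           by_dose = tibble::tibble(dose_mas = numeric(), metric = character(),
                                    t = numeric(), df = numeric(),
                                    p = numeric()),
           summary = tibble::tibble(metric = character(), mean_pct = numeric(),
                                    min_pct = numeric(), max_pct = numeric(),
                                    min_ci_width = numeric(),
                                    max_ci_width = numeric(),
                                    min_p = numeric()),
           config = config, seed = config$seed),
      class = "lodose_report"))
  }
  cells <- paired |>
    dplyr::group_by(.data$tissue, .data$dose_mas, .data$metric) |>
    dplyr::summarise(
      orig = mean(.data$original), sim = mean(.data$simulated),
      pct_discrepancy = percent_discrepancy(mean(.data$simulated),
                                            mean(.data$original)),
      ci = mean_difference_ci(.data$original, .data$simulated),
      t = paired_t_test(.data$simulated, .data$original),
      .groups = "drop") |>
    tidyr::unpack("ci") |>
    tidyr::unpack("t", names_sep = "_") |>
    dplyr::rename(p = "t_p", t = "t_t") |>
    dplyr::select(-"t_df")
  by_dose <- paired |>
    dplyr::group_by(.data$dose_mas, .data$metric) |>
    dplyr::summarise(t = paired_t_test(.data$simulated, .data$original),
                     .groups = "drop") |>
    tidyr::unpack("t")
  summary <- cells |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean_pct = mean(.data$pct_discrepancy),
                     min_pct = min(.data$pct_discrepancy),
                     max_pct = max(.data$pct_discrepancy),
                     min_ci_width = min(.data$ci_high - .data$ci_low),
                     max_ci_width = max(.data$ci_high - .data$ci_low),
                     min_p = min(.data$p), .groups = "drop")
  structure(list(measurements = measurements, cells = cells,
                 by_dose = by_dose, summary = summary,
                 config = config, seed = config$seed),
            class = "lodose_report")
}

#' @export
print.lodose_report <- function(x, ...) {
  cat("<lodose_report>\n")
  cat(sprintf("  parent %g mAs -> targets %s; %d ROIs x %d doses\n",
              x$config$source_mas,
              paste(x$config$target_mas, collapse = "/"),
              nrow(x$rois %||% data.frame()),
              length(x$config$target_mas)))
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf("  %s: mean discrepancy %+.1f%% (range %+.1f%% to %+.1f%%), min p = %.2f\n",
                s$metric, s$mean_pct, s$min_pct, s$max_pct, s$min_p))
  }
  invisible(x)
}

#' Tidy a discrepancy report
#'
#' `tidy()` returns the per-tissue/per-dose cell table (one row per tissue,
#' dose and metric, with both arms' values, percent discrepancy, paired-t
#' confidence interval and p-value). `glance()` returns a one-row summary
#' per run: mean and range of the percent discrepancies and the smallest
#' p-value per metric, in wide form.
#'
#' @param x a `lodose_report`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy lodose_report
#' @export
tidy.lodose_report <- function(x, ...) x$cells

#' @rdname tidy.lodose_report
#' @method glance lodose_report
#' @export
glance.lodose_report <- function(x, ...) {
  x$summary |>
    tidyr::pivot_wider(names_from = "metric",
                       values_from = c("mean_pct", "min_pct", "max_pct",
                                       "min_ci_width", "max_ci_width",
                                       "min_p")) |>
    dplyr::mutate(seed = x$seed, n_doses = length(x$config$target_mas))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot methods
#'
#' `autoplot.lodose_report` mirrors the study's tissue-by-dose bar chart:
#' ROI noise (or mean HU) for original versus simulated arms.
#' `autoplot.recon_image` renders the HU grid.
#'
#' @param object report or image.
#' @param metric `"noise"` or `"hu"`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot lodose_report
#' @export
autoplot.lodose_report <- function(object, metric = c("noise", "hu"), ...) {
  metric <- match.arg(metric)
  dat <- object$cells |>
    dplyr::filter(.data$metric == !!metric) |>
    tidyr::pivot_longer(c("orig", "sim"), names_to = "arm",
                        values_to = "value") |>
    dplyr::mutate(arm = dplyr::recode(.data$arm, orig = "original",
                                      sim = "simulated"))
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$dose_mas),
                                    y = .data$value, fill = .data$arm)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~tissue, scales = "free_y") +
    ggplot2::labs(x = "dose (mAs)",
                  y = if (metric == "noise") "ROI noise (HU sd)" else "mean HU",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.lodose_report
#' @method autoplot recon_image
#' @export
autoplot.recon_image <- function(object, ...) {
  n <- nrow(object$hu)
  dat <- tidyr::expand_grid(row = seq_len(n), col = seq_len(n))
  dat$hu <- as.vector(object$hu)[(dat$col - 1) * n + dat$row]
  ggplot2::ggplot(dat, ggplot2::aes(.data$col, -.data$row, fill = .data$hu)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(-1000, 1000),
                                 oob = scales_squish) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s, %g mAs (%s)", object$kernel,
                                  object$source_mas, object$provenance),
                  x = NULL, y = NULL, fill = "HU") +
    ggplot2::theme_void()
}

# minimal squish so scales is not a hard dependency
scales_squish <- function(x, range = c(0, 1), only.finite = TRUE) {
  pmin(pmax(x, range[1]), range[2])
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Write the report artifacts: reconstructions as NIfTI, cell and summary
# tables as CSV, one machine-readable JSON (seed + config hash recorded; no
# timestamps, so equal seeds give byte-identical summaries).
write_report <- function(report, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report$images)) {
    write_recon(report$images[[nm]], file.path(output_dir, nm))
  }
  utils::write.csv(report$cells, file.path(output_dir, "cells.csv"),
                   row.names = FALSE)
  utils::write.csv(report$measurements,
                   file.path(output_dir, "measurements.csv"),
                   row.names = FALSE)
  cfg <- report$config
  cfg$output_dir <- NULL
  jsonlite::write_json(
    list(seed = report$seed,
         config = unclass(cfg),
         config_hash = rlang::hash(unclass(cfg)),
         package_version = as.character(utils::packageVersion("lodosim")),
         summary = report$summary,
         by_dose = report$by_dose,
         cells = report$cells),
    file.path(output_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(output_dir)
}
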