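#' @title End-to-end runs: CSV results, decisions, plots, frame sequences
#' @name cli-report
NULL

#' Run configuration
#'
#' @param coil_type `"torso"`, `"headneck"` or `"body"`.
#' @param results_dir root directory accumulating QA results of one coil
#'   set over time (created if missing).
#' @param input_combined directory of a combined-element DICOM series.
#' @param input_uncombined directory of a "save uncombined" DICOM series.
#' @param input_sos directory of its sum-of-squares combined by-product.
#' @param coil_id coil identifier used for baselines, default
#'   `"<coil_type>:unnamed"`.
#' @param filter_label `"unfiltered"` or `"prescan"`.
#' @param date measurement date (text) used in file names and baselines.
#' @param criteria decision criterion (`"auto"`, `"sd"`, `"percent"`).
#' @param snr_correction SNR correction factor (see [compute_snr()]).
#' @param record append results to the baseline store under `results_dir`.
#' @param seed simulation seed (used by the CLI `simulate` command).
#' @return a `run_config` list.
#' @export
run_config <- function(coil_type = c("torso", "headneck", "body"),
                       results_dir, input_combined = NULL,
                       input_uncombined = NULL, input_sos = NULL,
                       coil_id = NULL, filter_label = "unfiltered",
                       date = "1970-01-01", criteria = "auto",
                       snr_correction = 1, record = FALSE, seed = 1L) {
  coil_type <- match.arg(coil_type)
  if (coil_type == "body" && filter_label == "prescan")
    stop("prescan normalization is not applicable for the body coil; ",
         "only unfiltered images are produced")
  structure(list(
    coil_type = coil_type, results_dir = results_dir,
    input_combined = input_combined, input_uncombined = input_uncombined,
    input_sos = input_sos,
    coil_id = coil_id %||% paste0(coil_type, ":unnamed"),
    filter_label = filter_label, date = date, criteria = criteria,
    snr_correction = snr_correction, record = record,
    seed = as.integer(seed)), class = "run_config")
}

#' Per-slice metric plot for a combined series
#'
#' Signal, noise, SNR and uniformity versus slice location, one panel per
#' quantity.
#'
#' @param metrics a `slice_metrics` data.frame.
#' @return a ggplot object.
#' @export
plot_combined_metrics <- function(metrics) {
  vars <- c(mean_signal = "signal (a.u.)", noise_sd = "noise SD (a.u.)",
            snr = "SNR", piu = "uniformity (%)")
  long <- do.call(rbind, lapply(names(vars), function(v)
    data.frame(slice_location = metrics$slice_location, panel = vars[[v]],
               value = metrics[[v]])))
  long$panel <- factor(long$panel, levels = unname(vars))
  ggplot2::ggplot(long, ggplot2::aes(x = slice_location, y = value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue", size = 1.2) +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "slice location (mm)", y = NULL) +
    ggplot2::theme_bw()
}

#' Per-element noise/signal/SNR plot
#' @param metrics an `element_metrics` data.frame.
#' @return a ggplot object (elements coloured, grouped panels by quantity).
#' @export
plot_element_metrics <- function(metrics) {
  vars <- c(noise_sd = "noise SD (a.u.)", mean_peak_signal = "signal (a.u.)",
            snr = "SNR")
  long <- do.call(rbind, lapply(names(vars), function(v)
    data.frame(slice_location = metrics$slice_location,
               element = metrics$element, panel = vars[[v]],
               value = metrics[[v]])))
  long$panel <- factor(long$panel, levels = unname(vars))
  ggplot2::ggplot(long, ggplot2::aes(x = slice_location, y = value,
                                     colour = element)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "slice location (mm)", y = NULL, colour = "element") +
    ggplot2::theme_bw()
}

# grey-image panel with optional ROI circle annotations
.draw_panel <- function(img, title, rois = list(), labels = NULL) {
  z <- t(img)[, rev(seq_len(nrow(img))), drop = FALSE]
  graphics::image(z, col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                  useRaster = TRUE, main = title)
  nr <- nrow(img); nc <- ncol(img)
  th <- seq(0, 2 * pi, length.out = 121)
  for (i in seq_along(rois)) {
    roi <- rois[[i]]
    # convert (row, col) pixel centres to the [0,1] plot coordinates
    cx <- (roi$center[2] - 1) / (nc - 1)
    cy <- 1 - (roi$center[1] - 1) / (nr - 1)
    graphics::lines(cx + roi$radius / (nc - 1) * cos(th),
                    cy + roi$radius / (nr - 1) * sin(th),
                    col = c("yellow", "cyan")[1 + (i - 1) %% 2], lwd = 2)
  }
  if (!is.null(labels))
    graphics::mtext(labels, side = 1, line = 0.2, cex = 0.7)
}

#' Write the per-slice review frame of one element
#'
#' One PNG per slice showing the Noise image with the transferred circular
#' ROI and the Signal image with the peak ROI, annotated with the computed
#' statistics — the reviewable "video" frame sequence.
#'
#' @param pair an `image_pair`.
#' @param row one row of an `element_metrics` data.frame.
#' @param path output PNG path.
#' @param sos_roi the transferred [circular_roi()] of this slice.
#' @return `path`, invisibly.
#' @export
render_element_frame <- function(pair, row, path, sos_roi) {
  grDevices::png(path, width = 640, height = 340)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mfrow = c(1, 2), mar = c(2, 1, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  .draw_panel(pair$noise,
              sprintf("%s noise, z = %+g mm", row$element,
                      row$slice_location),
              rois = list(sos_roi),
              labels = sprintf("SD = %.2f", row$noise_sd))
  .draw_panel(pair$signal, "signal",
              rois = list(circular_roi(c(row$peak_row, row$peak_col),
                                       5)),
              labels = sprintf("mean = %.1f  SNR = %.1f",
                               row$mean_peak_signal, row$snr))
  invisible(path)
}

#' Analyze a combined-element series end to end
#'
#' Loads the series, computes per-slice metrics, writes a tidy CSV and a
#' JSON copy, renders the metric plot, evaluates the measurement against
#' the baseline store under `results_dir`, and writes the decision report.
#'
#' @param config a [run_config()]; `input_combined` must be set.
#' @return list: `metrics`, `evaluation`, `files` (paths written),
#'   invisibly.
#' @export
run_combined <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$coil_type == "body" && config$filter_label == "prescan")
    stop("prescan normalization is not applicable for the body coil")
  if (is.null(config$input_combined))
    stop("config$input_combined is required")
  pairs <- load_series(config$input_combined, "combined")
  metrics <- analyze_combined_series(
    pairs, config = list(snr_correction = config$snr_correction))

  out <- file.path(config$results_dir, config$filter_label)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(out, paste0("metrics_", config$date, ".csv"))
  utils::write.csv(as.data.frame(metrics), csv, row.names = FALSE)
  jsonlite::write_json(as.data.frame(metrics),
                       sub("\\.csv$", ".json", csv), digits = NA,
                       pretty = TRUE)
  plot_file <- file.path(out, paste0("metrics_", config$date, ".png"))
  ggplot2::ggsave(plot_file, plot_combined_metrics(metrics),
                  width = 6, height = 8, dpi = 96)

  store <- qa_store(file.path(config$results_dir, "baselines"))
  evaluation <- evaluate_measurement(
    combined_baseline_values(metrics), store, config$coil_id,
    config$filter_label, date = config$date, criteria = config$criteria,
    record = config$record)
  dec_csv <- file.path(out, paste0("decisions_", config$date, ".csv"))
  utils::write.csv(evaluation$decisions, dec_csv, row.names = FALSE)

  invisible(list(metrics = metrics, evaluation = evaluation,
                 files = c(csv, plot_file, dec_csv)))
}

#' Analyze a "save uncombined" element series end to end
#'
#' Loads the uncombined and sum-of-squares series, computes per-element
#' metrics and peak-SNR summaries, writes CSVs, one PNG frame sequence per
#' element, the per-element plot, and evaluates peak SNR against the
#' baseline store.  For head/neck coils the physically absent VAP3/VPP3
#' channels are marked in the summary.
#'
#' @param config a [run_config()]; `input_uncombined` and `input_sos` must
#'   be set.
#' @param frames render the per-slice PNG frame sequences (slower).
#' @return list: `metrics`, `summary`, `evaluation`, `files`, invisibly.
#' @export
run_elements <- function(config, frames = TRUE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$input_uncombined) || is.null(config$input_sos))
    stop("config$input_uncombined and config$input_sos are required")
  unc <- load_series(config$input_uncombined, "uncombined")
  sos <- load_series(config$input_sos, "combined_sos")
  metrics <- analyze_element_series(
    unc, sos, config = list(snr_correction = config$snr_correction))
  summary <- summarize_peak_snr(metrics)
  if (config$coil_type == "headneck") {
    present <- attr(coil_elements("headneck"), "present")
    summary$present <- unname(present[summary$element])
  } else summary$present <- TRUE

  out <- file.path(config$results_dir, "elements")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(out, paste0("element_metrics_", config$date, ".csv"))
  utils::write.csv(as.data.frame(metrics), csv, row.names = FALSE)
  sum_csv <- file.path(out, paste0("element_summary_", config$date, ".csv"))
  utils::write.csv(as.data.frame(summary), sum_csv, row.names = FALSE)
  plot_file <- file.path(out, paste0("element_metrics_", config$date, ".png"))
  ggplot2::ggsave(plot_file, plot_element_metrics(metrics),
                  width = 6, height = 8, dpi = 96)

  files <- c(csv, sum_csv, plot_file)
  if (frames) {
    sos_loc <- vapply(sos, function(p) p$meta$slice_location, numeric(1))
    sos_roi <- lapply(sos, function(p)
      build_combined_roi(detect_phantom(p$signal), dim = dim(p$signal)))
    names(sos_roi) <- .loc_key(sos_loc)
    for (lab in names(unc)) {
      fdir <- file.path(out, "frames", lab)
      dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
      for (i in seq_along(unc[[lab]])) {
        p <- unc[[lab]][[i]]
        key <- .loc_key(p$meta$slice_location)
        row <- metrics[metrics$element == lab &
                         .loc_key(metrics$slice_location) == key, ]
        fp <- file.path(fdir, sprintf("frame_%03d.png", i))
        render_element_frame(p, row[1, ], fp, sos_roi[[key]])
        files <- c(files, fp)
      }
    }
  }

  store <- qa_store(file.path(config$results_dir, "baselines"))
  evaluation <- evaluate_measurement(
    element_baseline_values(summary), store, config$coil_id, "elements",
    date = config$date, criteria = config$criteria, record = config$record)
  dec_csv <- file.path(out, paste0("decisions_", config$date, ".csv"))
  utils::write.csv(evaluation$decisions, dec_csv, row.names = FALSE)
  files <- c(files, dec_csv)

  invisible(list(metrics = metrics, summary = summary,
                 evaluation = evaluation, files = files))
}
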