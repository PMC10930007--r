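#' @title Per-slice SNR and uniformity for combined-element series
#' @description
#' NEMA-style construction: the mean pixel intensity inside the Signal-image
#' ROI divided by the sample SD of pixel intensity inside the same ROI
#' applied to the paired Noise image gives the per-slice SNR; the ROI
#' extremes of the Signal image give percent image uniformity
#' PIU = 100 (1 - (S_max - S_min) / (S_max + S_min)).
#' @name combined-metrics
NULL

#' Signal-to-noise ratio from ROI statistics
#'
#' `snr = correction * mean_signal / noise_sd`.  The default correction is
#' 1 (plain ratio of the two ROI statistics); `correction = 0.655` converts
#' a Rayleigh noise-image SD into the underlying per-channel sigma for
#' NEMA-strict reporting.  Note the correction rescales all baselines, so
#' it must be kept constant within a longitudinal series.
#'
#' @param mean_signal mean over the Signal-image ROI (a.u., >= 0).
#' @param noise_sd sample SD over the Noise-image ROI (a.u., > 0).
#' @param correction multiplicative correction factor.
#' @return dimensionless SNR (vectorised).
#' @export
compute_snr <- function(mean_signal, noise_sd, correction = 1) {
  if (any(noise_sd <= 0))
    stop("zero-noise error: noise_sd must be > 0 (corrupt Noise image?)")
  correction * mean_signal / noise_sd
}

#' Percent image uniformity
#'
#' `PIU = 100 * (1 - (s_max - s_min) / (s_max + s_min))`; 100 for a
#' perfectly uniform ROI, 0 when the minimum is zero.
#'
#' @param s_max,s_min maximum and minimum pixel value inside the
#'   Signal-image ROI (`s_max >= s_min >= 0`, `s_max > 0`).
#' @return PIU in percent, in \[0, 100\] (vectorised).
#' @export
compute_piu <- function(s_max, s_min) {
  if (any(s_max <= 0)) stop("undefined PIU: s_max must be > 0")
  if (any(s_min < 0) || any(s_max < s_min))
    stop("PIU requires s_max >= s_min >= 0")
  100 * (1 - (s_max - s_min) / (s_max + s_min))
}

#' Analyze a combined-element series
#'
#' Per slice: segment the phantom on the Signal image, build the circular
#' ROI (diameter 90% of the phantom width), take mean/min/max of the Signal
#' ROI and the sample SD of the same ROI on the Noise image, and derive SNR
#' and PIU.
#'
#' @param pairs list of `image_pair`s (from [load_series()] or
#'   [make_combined_series()]).
#' @param config list of options: `snr_correction` (default 1),
#'   `threshold_method` (`"otsu"`/`"fraction"`), `threshold_fraction`,
#'   `roi_diameter_fraction` (default 0.9).
#' @return a data.frame (class `slice_metrics`), one row per slice ordered
#'   by slice location: `slice_location`, `mean_signal`, `noise_sd`, `snr`,
#'   `s_max`, `s_min`, `piu`, `roi_row`, `roi_col`, `roi_radius`.
#' @export
analyze_combined_series <- function(pairs, config = list()) {
  stopifnot(length(pairs) >= 1)
  corr <- config$snr_correction %||% 1
  method <- config$threshold_method %||% "otsu"
  frac <- config$threshold_fraction %||% 0.25
  dfrac <- config$roi_diameter_fraction %||% 0.9

  rows <- lapply(pairs, function(p) {
    loc <- p$meta$slice_location
    geom <- tryCatch(
      detect_phantom(p$signal, method = method, fraction = frac),
      error = function(e) stop("slice ", .loc_key(loc), " mm: ",
                               conditionMessage(e), call. = FALSE))
    roi <- build_combined_roi(geom, dim = dim(p$signal),
                              diameter_fraction = dfrac)
    sv <- roi_pixels(p$signal, roi)
    nv <- roi_pixels(p$noise, roi)
    data.frame(slice_location = loc,
               mean_signal = mean(sv),
               noise_sd = stats::sd(nv),
               snr = compute_snr(mean(sv), stats::sd(nv), corr),
               s_max = max(sv), s_min = min(sv),
               piu = compute_piu(max(sv), min(sv)),
               roi_row = roi$center[1], roi_col = roi$center[2],
               roi_radius = roi$radius)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$slice_location), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("slice_metrics", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
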