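#' @title Per-element analysis of "save uncombined" series
#' @description
#' For each coil element and slice: noise is the sample SD inside the
#' circular ROI transferred from the sum-of-squares combined by-product
#' series; signal is the mean inside a small (5 px radius) ROI placed at
#' the intensity peak of the box-smoothed Signal image, restricted to the
#' phantom so the ROI never leaves it; SNR is their ratio.  Per-element
#' summaries average the three slices where SNR peaks (+/-110, 130, 150 mm
#' depending on the element group's axial side).
#' @name element-metrics
NULL

#' Box-average smoothing with replicate borders
#'
#' Uniform `window x window` mean filter.  For an even window the anchor is
#' biased toward the top-left: output(i, j) averages rows
#' `i - floor(window/2) ... i + window - 1 - floor(window/2)` (same for
#' columns), with out-of-image indices replicated from the nearest edge.
#' Implemented with padded integral images, so it matches a naive
#' sliding-window mean exactly.
#'
#' @param signal_pixels numeric matrix.
#' @param window filter size in px (>= 1).
#' @return smoothed matrix of the same dimensions.
#' @export
smooth_signal <- function(signal_pixels, window = 10L) {
  stopifnot(is.matrix(signal_pixels), window >= 1L)
  w <- as.integer(window)
  if (w == 1L) return(signal_pixels)
  a <- w %/% 2L           # extent above/left of the anchor
  b <- w - 1L - a         # extent below/right
  nr <- nrow(signal_pixels); nc <- ncol(signal_pixels)
  ri <- pmin(pmax(seq(1L - a, nr + b), 1L), nr)
  ci <- pmin(pmax(seq(1L - a, nc + b), 1L), nc)
  pad <- signal_pixels[ri, ci, drop = FALSE]
  ii <- rbind(0, apply(rbind(0, apply(pad, 2, cumsum)), 1, cumsum))
  ii <- t(ii)  # ii[i+1, j+1] = sum of pad[1:i, 1:j]
  i0 <- seq_len(nr); j0 <- seq_len(nc)
  (ii[i0 + w, j0 + w, drop = FALSE] - ii[i0, j0 + w, drop = FALSE] -
     ii[i0 + w, j0, drop = FALSE] + ii[i0, j0, drop = FALSE]) / (w * w)
}

#' Locate the peak-signal ROI of an element image
#'
#' The argmax of the smoothed Signal image is searched inside the phantom
#' mask eroded by `roi_radius`, which guarantees the resulting ROI lies
#' entirely inside the phantom; the ROI (radius 5 px, i.e. 5.86 mm at
#' FOV 300 mm / matrix 256) is then applied to the *original* image.
#' Ties are broken by smallest (row, col) in lexicographic order.
#'
#' @param signal_pixels numeric matrix (original, unsmoothed).
#' @param phantom_mask logical matrix (e.g. from the sum-of-squares
#'   combined series segmentation).
#' @param roi_radius peak-ROI radius in px.
#' @param window smoothing window in px (see [smooth_signal()]).
#' @return list with `peak_center` (row, col) and `roi` ([circular_roi()]).
#' @export
locate_peak_roi <- function(signal_pixels, phantom_mask, roi_radius = 5L,
                            window = 10L) {
  stopifnot(identical(dim(signal_pixels), dim(phantom_mask)))
  if (!any(phantom_mask)) stop("phantom mask is empty")
  brush <- EBImage::makeBrush(2L * as.integer(roi_radius) + 1L,
                              shape = "disc")
  eroded <- EBImage::imageData(
    EBImage::erode(EBImage::Image(phantom_mask * 1), brush)) > 0.5
  # the ROI must also fit inside the image frame
  nr <- nrow(eroded); nc <- ncol(eroded)
  r <- ceiling(roi_radius)
  if (r >= 1) {
    eroded[c(seq_len(min(r, nr)), seq(max(nr - r + 1L, 1L), nr)), ] <- FALSE
    eroded[, c(seq_len(min(r, nc)), seq(max(nc - r + 1L, 1L), nc))] <- FALSE
  }
  if (!any(eroded))
    stop("phantom too small: mask eroded by the ROI radius is empty")
  sm <- smooth_signal(signal_pixels, window = window)
  sm[!eroded] <- -Inf
  mx <- max(sm)
  hits <- which(sm == mx, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  peak <- as.numeric(hits[1, ])
  list(peak_center = peak, roi = circular_roi(peak, roi_radius))
}

#' Analyze a "save uncombined" element series
#'
#' The phantom is segmented on each Signal image of the sum-of-squares
#' combined by-product series; its circular ROI is transferred to the
#' element Noise images of the same slice (noise SD is therefore computed
#' on identical pixels for all elements of a slice), and the peak ROI is
#' located on each element Signal image within the sum-of-squares phantom
#' mask.
#'
#' @param uncombined named list element label -> list of `image_pair`s
#'   (from [load_series()] or [make_element_series()]).
#' @param sos_combined list of `image_pair`s of the sum-of-squares
#'   combined by-product series.
#' @param config list: `snr_correction` (default 1), `peak_roi_radius`
#'   (default 5), `smooth_window` (default 10), `threshold_method`,
#'   `threshold_fraction`, `roi_diameter_fraction`.
#' @return data.frame (class `element_metrics`), one row per element and
#'   slice: `element`, `slice_location`, `noise_sd`, `peak_row`,
#'   `peak_col`, `mean_peak_signal`, `snr`, plus the phantom centre
#'   (`phantom_row`, `phantom_col`) used for position derivation.
#' @export
analyze_element_series <- function(uncombined, sos_combined, config = list()) {
  stopifnot(length(uncombined) >= 1, length(sos_combined) >= 1)
  corr <- config$snr_correction %||% 1
  prad <- config$peak_roi_radius %||% 5L
  win <- config$smooth_window %||% 10L
  method <- config$threshold_method %||% "otsu"
  frac <- config$threshold_fraction %||% 0.25
  dfrac <- config$roi_diameter_fraction %||% 0.9

  sos_loc <- vapply(sos_combined, function(p) p$meta$slice_location,
                    numeric(1))
  sos_key <- .loc_key(sos_loc)
  # per-slice geometry and transferred ROI from the sum-of-squares series
  sos_geom <- lapply(sos_combined, function(p)
    detect_phantom(p$signal, method = method, fraction = frac))
  sos_roi <- lapply(seq_along(sos_combined), function(i)
    build_combined_roi(sos_geom[[i]], dim = dim(sos_combined[[i]]$signal),
                       diameter_fraction = dfrac))
  names(sos_geom) <- names(sos_roi) <- sos_key

  rows <- list()
  for (lab in names(uncombined)) {
    for (p in uncombined[[lab]]) {
      key <- .loc_key(p$meta$slice_location)
      if (!key %in% sos_key)
        stop("alignment error: slice ", key, " mm of element ", lab,
             " has no match in the sum-of-squares combined series")
      geom <- sos_geom[[key]]
      nv <- roi_pixels(p$noise, sos_roi[[key]])
      pk <- locate_peak_roi(p$signal, geom$mask, roi_radius = prad,
                            window = win)
      ms <- mean(roi_pixels(p$signal, pk$roi))
      rows[[length(rows) + 1L]] <- data.frame(
        element = lab, slice_location = p$meta$slice_location,
        noise_sd = stats::sd(nv),
        peak_row = pk$peak_center[1], peak_col = pk$peak_center[2],
        mean_peak_signal = ms,
        snr = compute_snr(ms, stats::sd(nv), corr),
        phantom_row = geom$center[1], phantom_col = geom$center[2])
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$element, out$slice_location), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("element_metrics", "data.frame")
  out
}

# axial side of an element group from the third letter of its label
.group_side <- function(label) {
  letter <- substr(label, 3, 3)
  if (letter == "P") +1 else if (letter == "S") -1
  else stop("cannot derive axial side from element label ", label)
}

#' Summarize peak SNR per element
#'
#' Selects the three slices where element SNR peaks — +110/+130/+150 mm for
#' superior groups (third letter P) and -110/-130/-150 mm for inferior
#' groups (third letter S) — and reports their mean SNR and its SD.
#' Slice matching is nearest-neighbour within `tol` mm.
#'
#' @param metrics an `element_metrics` data.frame
#'   ([analyze_element_series()]).
#' @param peak_locations magnitudes of the summary slice locations in mm.
#' @param tol slice-matching tolerance in mm.
#' @return data.frame (class `element_summary`): `element`, `group`,
#'   `peak_snr_mean`, `peak_snr_sd`, `slices_used`.
#' @export
summarize_peak_snr <- function(metrics, peak_locations = c(110, 130, 150),
                               tol = 1) {
  stopifnot(is.data.frame(metrics))
  rows <- lapply(split(metrics, metrics$element), function(m) {
    lab <- m$element[1]
    side <- .group_side(lab)
    target <- side * peak_locations
    snr <- vapply(target, function(t) {
      d <- abs(m$slice_location - t)
      if (min(d) > tol)
        stop("coverage error: element ", lab, " has no slice within ", tol,
             " mm of ", t, " mm")
      m$snr[which.min(d)]
    }, numeric(1))
    data.frame(element = lab, group = substr(lab, 1, 3),
               peak_snr_mean = mean(snr), peak_snr_sd = stats::sd(snr),
               slices_used = paste(sprintf("%+g", target), collapse = "/"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("element_summary", "data.frame")
  out
}

#' Derive the physical position of one coil element
#'
#' The axial side (superior/inferior) is the sign of the slice location
#' with maximal mean peak signal; the in-plane position is the coarse
#' angular sector (octant, 45 degrees wide, octant 1 centred at 0 = +x) of
#' the peak centre relative to the phantom centre at that slice.  An
#' element whose SNR never reaches `snr_floor` is reported as
#' undetectable (e.g. a noise-only channel).
#'
#' @param metrics rows of an `element_metrics` data.frame for one element.
#' @param snr_floor minimum SNR for the position to be considered real.
#' @return list: `axial` (`"superior"`, `"inferior"` or `"undetectable"`),
#'   `octant` (1-8 or NA), `angle_deg` (0-360 or NA).
#' @export
derive_element_position <- function(metrics, snr_floor = 5) {
  stopifnot(is.data.frame(metrics), length(unique(metrics$element)) == 1)
  if (max(metrics$snr) < snr_floor)
    return(list(axial = "undetectable", octant = NA_integer_,
                angle_deg = NA_real_))
  i <- which.max(metrics$mean_peak_signal)
  axial <- if (metrics$slice_location[i] >= 0) "superior" else "inferior"
  dx <- metrics$peak_col[i] - metrics$phantom_col[i]
  dy <- metrics$phantom_row[i] - metrics$peak_row[i]  # y up
  ang <- (atan2(dy, dx) * 180 / pi) %% 360
  octant <- (floor((ang + 22.5) / 45) %% 8) + 1
  list(axial = axial, octant = as.integer(octant), angle_deg = ang)
}
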