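#' @title Phantom segmentation and circular analysis ROI
#' @description
#' The phantom is detected on each Signal image by thresholding (Otsu by
#' default), filling holes and keeping the largest connected component.
#' The phantom centre is the midpoint of the component's horizontal and
#' vertical extents, and the analysis ROI is a circle at that centre with
#' diameter 90% of the phantom width.  Coordinates are 1-based (row, col)
#' with pixel centres at integer positions; circle membership is tested on
#' pixel-centre Euclidean distance.
#' @name segmentation-roi
NULL

#' Detect the phantom on a Signal image
#'
#' @param signal_pixels numeric matrix.
#' @param method `"otsu"` (threshold chosen by Otsu's method on the full
#'   image, scale invariant) or `"fraction"` (threshold at
#'   `fraction * max`).
#' @param fraction threshold fraction of the image maximum for
#'   `method = "fraction"`.
#' @return a `phantom_geometry` object: `mask` (logical matrix), `center`
#'   (row, col; possibly half-integer), `width` and `height` (px extents).
#' @export
detect_phantom <- function(signal_pixels, method = c("otsu", "fraction"),
                           fraction = 0.25) {
  method <- match.arg(method)
  stopifnot(is.matrix(signal_pixels), is.numeric(signal_pixels))
  rng <- range(signal_pixels)
  if (!all(is.finite(rng)) || rng[1] == rng[2])
    stop("no phantom detected: image is constant")
  mask <- if (method == "otsu") {
    norm <- (signal_pixels - rng[1]) / (rng[2] - rng[1])
    th <- EBImage::otsu(EBImage::Image(norm))
    norm > th
  } else {
    signal_pixels > fraction * rng[2]
  }
  fg <- mean(mask)
  if (fg < 0.01 || fg > 0.95)
    stop("no phantom detected: foreground fraction ", signif(fg, 3),
         " outside [0.01, 0.95]")
  lab <- EBImage::bwlabel(EBImage::fillHull(EBImage::Image(mask * 1)))
  lab <- EBImage::imageData(lab)
  counts <- tabulate(lab[lab > 0])
  mask <- lab == which.max(counts)
  rows <- which(apply(mask, 1, any))
  cols <- which(apply(mask, 2, any))
  width <- max(cols) - min(cols) + 1L
  height <- max(rows) - min(rows) + 1L
  if (width < 8L || height < 8L)
    stop("phantom too small: width/height must be >= 8 px (got ",
         width, " x ", height, ")")
  structure(list(
    mask = mask,
    center = c((min(rows) + max(rows)) / 2, (min(cols) + max(cols)) / 2),
    width = width, height = height), class = "phantom_geometry")
}

#' Circular ROI constructor
#' @param center numeric (row, col), pixel-centre coordinates (1-based).
#' @param radius radius in px (> 0).
#' @return a `circular_roi` object.
#' @export
circular_roi <- function(center, radius) {
  if (radius <= 0) stop("roi radius must be > 0")
  structure(list(center = as.numeric(center), radius = radius),
            class = "circular_roi")
}

#' Build the combined-analysis ROI from a phantom geometry
#'
#' Circle at the phantom centre with diameter 90% of the phantom width
#' (radius = 0.45 x width).
#'
#' @param geometry a `phantom_geometry` from [detect_phantom()], or any
#'   list with `center` and `width`.
#' @param dim image dimensions (rows, cols) for the in-bounds check;
#'   defaults to the geometry mask dimensions.
#' @param diameter_fraction ROI diameter as fraction of the phantom width.
#' @return a [circular_roi()].
#' @export
build_combined_roi <- function(geometry, dim = base::dim(geometry$mask),
                               diameter_fraction = 0.9) {
  if (geometry$width < 8) stop("phantom geometry invalid: width < 8 px")
  roi <- circular_roi(geometry$center, diameter_fraction / 2 * geometry$width)
  if (!is.null(dim)) .check_roi_bounds(roi, dim)
  roi
}

.check_roi_bounds <- function(roi, dim) {
  if (roi$center[1] - roi$radius < 0.5 || roi$center[1] + roi$radius > dim[1] + 0.5 ||
      roi$center[2] - roi$radius < 0.5 || roi$center[2] + roi$radius > dim[2] + 0.5)
    stop("roi exceeds image bounds")
  invisible(roi)
}

#' Logical membership mask of a circular ROI
#' @param roi a [circular_roi()].
#' @param dim image dimensions (rows, cols).
#' @return logical matrix: pixel centres within `radius` of the ROI centre.
#' @export
roi_mask <- function(roi, dim) {
  dr <- (seq_len(dim[1]) - roi$center[1])^2
  dc <- (seq_len(dim[2]) - roi$center[2])^2
  outer(dr, dc, `+`) <= roi$radius^2
}

#' Extract the pixel values inside a circular ROI
#' @param image numeric matrix.
#' @param roi a [circular_roi()].
#' @return numeric vector of member pixel values.
#' @export
roi_pixels <- function(image, roi) {
  .check_roi_bounds(roi, dim(image))
  image[roi_mask(roi, dim(image))]
}
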