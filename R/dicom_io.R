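#' @title Series ingest: directory of DICOMs -> validated image pairs
#' @name dicom-io
NULL

#' Classify the Signal and Noise member of a slice pair
#'
#' The Signal image (RF on) has overall higher intensity, so the member
#' with the larger maximum pixel value is Signal.  On an exact tie the
#' acquisition order decides: the first-acquired image (lower
#' InstanceNumber, passed via `order_a`/`order_b`) is Signal.
#'
#' @param image_a,image_b numeric matrices of one slice/element group.
#' @param order_a,order_b acquisition ordinals (e.g. InstanceNumber).
#' @return list with `signal` and `noise` matrices and `signal_first`
#'   (TRUE if `image_a` was classified as Signal).
#' @export
assign_signal_noise <- function(image_a, image_b, order_a = 1L, order_b = 2L) {
  stopifnot(identical(dim(image_a), dim(image_b)))
  ma <- max(image_a); mb <- max(image_b)
  a_is_signal <- if (ma != mb) ma > mb else order_a < order_b
  if (a_is_signal) list(signal = image_a, noise = image_b, signal_first = TRUE)
  else list(signal = image_b, noise = image_a, signal_first = FALSE)
}

# slice grouping key: locations rounded to 0.1 mm (negative zero folded)
.loc_key <- function(x) {
  v <- round(x, 1)
  v[v == 0] <- 0
  sprintf("%.1f", v)
}

#' Load a DICOM series directory into image pairs
#'
#' Reads every `*.dcm` file, groups images by (slice location, element
#' label), validates that each group holds exactly two images of identical
#' shape and pixel spacing, classifies Signal vs Noise
#' ([assign_signal_noise()]), and sorts pairs by slice location.  The
#' result is independent of filesystem enumeration order.
#'
#' @param directory path containing the DICOM files of a single series.
#' @param expected_kind `"combined"`, `"combined_sos"` (both return a flat
#'   list of pairs) or `"uncombined"` (returns a named list: element ->
#'   pairs).
#' @return list of `image_pair` objects, or for `"uncombined"` a named list
#'   of such lists keyed by element label.
#' @export
load_series <- function(directory,
                        expected_kind = c("combined", "uncombined",
                                          "combined_sos")) {
  expected_kind <- match.arg(expected_kind)
  files <- sort(list.files(directory, pattern = "\\.dcm$", ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) == 0) stop("no DICOM files found in ", directory)
  imgs <- lapply(files, dicom_read)

  locs <- vapply(imgs, function(i) i$meta$slice_location, numeric(1))
  if (anyNA(locs)) stop("missing slice location in series ", directory)
  els <- vapply(imgs, function(i) i$meta$coil_name, character(1))
  if (expected_kind == "uncombined" && anyNA(els))
    stop("uncombined series has images without an element label")

  ps <- t(vapply(imgs, function(i) i$meta$pixel_spacing[1:2], numeric(2)))
  dims <- t(vapply(imgs, function(i) c(i$meta$rows, i$meta$cols), numeric(2)))
  if (nrow(unique(ps)) > 1 || nrow(unique(dims)) > 1)
    stop("inconsistent series: mixed pixel spacing or matrix size in ",
         directory)

  key <- paste(.loc_key(locs),
               ifelse(is.na(els), "", els), sep = "|")
  groups <- split(seq_along(imgs), key)

  bad <- names(groups)[lengths(groups) != 2L]
  if (length(bad) > 0)
    stop("missing pair: expected exactly 2 images per slice/element group, ",
         "offending group(s): ", paste(bad, collapse = "; "))

  make_pair <- function(idx) {
    a <- imgs[[idx[1]]]; b <- imgs[[idx[2]]]
    sn <- assign_signal_noise(a$pixels, b$pixels,
                              order_a = a$meta$instance_number,
                              order_b = b$meta$instance_number)
    .image_pair(sn$signal, sn$noise, meta = list(
      slice_location = a$meta$slice_location,
      element = if (is.na(a$meta$coil_name)) NA_character_
                else a$meta$coil_name,
      filter_label = a$meta$series_description,
      series_kind = expected_kind,
      pixel_spacing = a$meta$pixel_spacing))
  }

  pairs <- lapply(groups, make_pair)
  locs_g <- vapply(pairs, function(p) p$meta$slice_location, numeric(1))
  if (expected_kind == "uncombined") {
    els_g <- vapply(pairs, function(p) p$meta$element, character(1))
    out <- lapply(split(seq_along(pairs), els_g), function(ix) {
      sub <- pairs[ix][order(locs_g[ix])]
      names(sub) <- NULL
      sub
    })
    return(out)
  }
  pairs <- pairs[order(locs_g)]
  names(pairs) <- NULL
  pairs
}
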