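#' @title Synthetic phantom acquisition generator
#' @description
#' Simulates the multi-slice spin-echo QA acquisition of a cylindrical
#' phantom: for every axial slice one Signal image (RF on) and one Noise
#' image (RF off), either for combined coil elements or per element
#' ("save uncombined") together with the sum-of-squares combined
#' by-product.  Ground truth (axial profile, noise level per slice,
#' element sensitivity models) is attached so downstream estimators can be
#' validated, and coil-element faults (dead, noisy) can be injected.
#' @name synthetic-phantom
NULL

#' Acquisition design
#'
#' Geometry of the simulated multi-slice axial acquisition.  Defaults match
#' the QA protocol: 18 axial slices of 10 mm thickness with 100% gap
#' (centre-to-centre spacing twice the thickness), a 300 mm field of view on
#' a 256 matrix, and a 135 mm diameter cylindrical phantom centred in-plane.
#'
#' @param n_slices number of axial slices (>= 1).
#' @param slice_thickness slice thickness in mm (> 0).
#' @param gap_fraction inter-slice gap as a fraction of the thickness
#'   (1 = 100% gap).
#' @param fov in-plane field of view in mm (square).
#' @param matrix acquisition matrix size in px (square, >= 16).
#' @param phantom_diameter phantom cross-section diameter in mm.
#' @param center_offset length-2 numeric, in-plane (x, y) offset of the
#'   phantom centre from isocenter in mm (x right, y up).
#' @return an `acquisition_design` object (list).
#' @export
acquisition_design <- function(n_slices = 18L, slice_thickness = 10,
                               gap_fraction = 1, fov = 300, matrix = 256L,
                               phantom_diameter = 135,
                               center_offset = c(0, 0)) {
  if (n_slices < 1L) stop("invalid design: n_slices must be >= 1")
  if (slice_thickness <= 0) stop("invalid design: slice_thickness must be > 0")
  if (matrix < 16L) stop("invalid design: matrix must be >= 16 px")
  if (gap_fraction < 0) stop("invalid design: gap_fraction must be >= 0")
  if (fov <= 0 || phantom_diameter <= 0)
    stop("invalid design: fov and phantom_diameter must be > 0")
  structure(list(
    n_slices = as.integer(n_slices),
    slice_thickness = slice_thickness,
    gap_fraction = gap_fraction,
    fov = fov,
    matrix = as.integer(matrix),
    phantom_diameter = phantom_diameter,
    center_offset = center_offset,
    pixel_spacing = fov / matrix
  ), class = "acquisition_design")
}

#' Slice-centre locations
#'
#' Slice centres are spaced `slice_thickness * (1 + gap_fraction)` apart and
#' placed symmetrically about isocenter, so the default 18-slice, 10 mm,
#' 100%-gap protocol spans centre locations -170 ... +170 mm.
#'
#' @param design an [acquisition_design()].
#' @return numeric vector of slice-centre locations in mm, ascending.
#' @export
slice_positions <- function(design) {
  stopifnot(inherits(design, "acquisition_design"))
  spacing <- design$slice_thickness * (1 + design$gap_fraction)
  (seq_len(design$n_slices) - (design$n_slices + 1) / 2) * spacing
}

#' Magnitude-noise model
#'
#' Receiver noise is parameterised by a per-channel Gaussian sigma that is
#' boosted by a constant factor for slices within `boost_extent` mm of
#' isocenter (the split-magnet design elevates noise on the central slices).
#' The physical default distribution is `"rayleigh"`: two i.i.d. Gaussian
#' quadrature channels, so noise-only pixels are Rayleigh and signal pixels
#' Rician, all nonnegative.  The `"gaussian"` option adds a single signed
#' Gaussian channel instead; it is an analytic diagnostic mode in which the
#' sample SD of a noise-image ROI estimates `base_sigma` exactly (such
#' images are signed, not magnitude images).
#'
#' @param base_sigma per-channel noise sigma, a.u. (> 0).
#' @param central_boost multiplicative boost inside the central band (>= 1).
#' @param boost_extent half-extent of the central band in mm.
#' @param distribution `"rayleigh"` (magnitude, default) or `"gaussian"`.
#' @return a `noise_model` object (list).
#' @export
noise_model <- function(base_sigma = 5, central_boost = 1.5, boost_extent = 30,
                        distribution = c("rayleigh", "gaussian")) {
  if (base_sigma <= 0) stop("invalid noise model: base_sigma must be > 0")
  if (central_boost < 1) stop("invalid noise model: central_boost must be >= 1")
  structure(list(base_sigma = base_sigma, central_boost = central_boost,
                 boost_extent = boost_extent,
                 distribution = match.arg(distribution)),
            class = "noise_model")
}

#' Per-channel noise sigma at a slice location
#' @param noise a [noise_model()].
#' @param slice_location slice centre in mm (vectorised).
#' @return numeric vector of sigmas.
#' @export
noise_sigma_at <- function(noise, slice_location) {
  noise$base_sigma *
    ifelse(abs(slice_location) <= noise$boost_extent, noise$central_boost, 1)
}

#' Coil element sensitivity model
#'
#' One receive element is modelled by a separable sensitivity: an in-plane
#' exponential falloff from a point on the phantom rim at `in_plane_angle`,
#' times a Gaussian axial falloff centred at `axial_center` (around +/-90 mm
#' for the superior/inferior element groups).  Faults: `"dead"` replaces the
#' axial response by a small flat residual and triples the element noise;
#' `"noisy"` leaves the signal untouched and raises noise by 50%.
#'
#' @param label element name, e.g. `"VAP1"`; unique within a coil model.
#' @param axial_center axial position of peak sensitivity in mm.
#' @param in_plane_angle angle of the element on the phantom circumference,
#'   degrees (0 = +x/right, counter-clockwise, y up).
#' @param sensitivity_scale peak signal amplitude, a.u. (>= 0).
#' @param axial_width Gaussian axial falloff scale in mm.
#' @param inplane_falloff in-plane exponential decay length in mm.
#' @param noise_sigma per-channel noise sigma of this element, a.u. (> 0).
#' @param fault `"none"`, `"dead"` or `"noisy"`.
#' @return an `element_model` object (list).
#' @export
element_model <- function(label, axial_center, in_plane_angle,
                          sensitivity_scale = 600, axial_width = 75,
                          inplane_falloff = 60, noise_sigma = 10,
                          fault = c("none", "dead", "noisy")) {
  fault <- match.arg(fault)
  if (sensitivity_scale < 0) stop("sensitivity_scale must be >= 0")
  if (noise_sigma <= 0) stop("noise_sigma must be > 0")
  structure(list(label = label, axial_center = axial_center,
                 in_plane_angle = in_plane_angle,
                 sensitivity_scale = sensitivity_scale,
                 axial_width = axial_width, inplane_falloff = inplane_falloff,
                 noise_sigma = noise_sigma, fault = fault),
            class = "element_model")
}

#' Coil element table for a coil type
#'
#' Twelve acquisition channels in four groups of three (VAP, VAS, VPP,
#' VPS); the third letter encodes the axial side (P = superior, +90 mm;
#' S = inferior, -90 mm).  VA groups sit on the bottom coil half (lower
#' rim), VP groups on the top.  For the head/neck coil the VAP3 and VPP3
#' channels exist in the data but have no physical element: they are
#' modelled as zero sensitivity with low receiver noise.  `fault` can name
#' elements to degrade, e.g. `c(VAS1 = "dead")`.
#'
#' @param coil_type `"torso"` or `"headneck"`.
#' @param fault named character vector mapping element labels to
#'   `"dead"`/`"noisy"`.
#' @return list of [element_model()]s with a `present` attribute (logical,
#'   FALSE for physically absent channels).
#' @export
coil_elements <- function(coil_type = c("torso", "headneck"), fault = NULL) {
  coil_type <- match.arg(coil_type)
  groups <- c("VAP", "VAS", "VPP", "VPS")
  # bottom (VA*) elements low on the rim, top (VP*) elements high
  angles <- list(VAP = c(210, 270, 330), VAS = c(210, 270, 330),
                 VPP = c(30, 90, 150), VPS = c(30, 90, 150))
  out <- list(); present <- logical(0)
  for (g in groups) {
    side <- if (substr(g, 3, 3) == "P") 90 else -90
    for (i in 1:3) {
      lab <- paste0(g, i)
      absent <- coil_type == "headneck" && lab %in% c("VAP3", "VPP3")
      f <- "none"
      if (!is.null(fault) && lab %in% names(fault)) f <- unname(fault[[lab]])
      out[[lab]] <- element_model(
        label = lab, axial_center = side, in_plane_angle = angles[[g]][i],
        sensitivity_scale = if (absent) 0 else 600,
        noise_sigma = if (absent) 1.5 else 10,
        fault = f)
      present <- c(present, !absent)
    }
  }
  attr(out, "present") <- stats::setNames(present, names(out))
  out
}

#' Default combined-element axial signal profile
#'
#' Unfiltered combined images of the receive-only coils peak near +/-90 mm
#' (superior for torso, inferior for head/neck); prescan-normalised images
#' and the body coil show a bell shape centred at isocenter.
#'
#' @param coil_type `"torso"`, `"headneck"` or `"body"`.
#' @param filter_label `"unfiltered"` or `"prescan"`.
#' @return function mapping slice location (mm) to in-slice intensity (a.u.).
#' @export
coil_signal_profile <- function(coil_type = c("torso", "headneck", "body"),
                                filter_label = c("unfiltered", "prescan")) {
  coil_type <- match.arg(coil_type)
  filter_label <- match.arg(filter_label)
  if (coil_type == "body") {
    if (filter_label == "prescan")
      stop("prescan normalization is not applicable for the body coil")
    return(function(z) 1050 * exp(-(z / 160)^2))
  }
  if (filter_label == "prescan") {
    peak <- if (coil_type == "torso") 800 else 650
    return(function(z) peak * exp(-(z / 160)^2))
  }
  s <- if (coil_type == "torso") 1 else -1  # peak side of the main lobe
  function(z) 680 * exp(-((z - s * 90) / 100)^2) +
    430 * exp(-((z + s * 90) / 100)^2)
}

# in-plane pixel-centre coordinates in mm (x right, y up), 1-based matrix
.plane_coords <- function(design) {
  n <- design$matrix; ps <- design$pixel_spacing
  x <- (seq_len(n) - (n + 1) / 2) * ps
  list(x = matrix(x, n, n, byrow = TRUE),
       y = matrix(rev(x), n, n, byrow = FALSE))
}

# boolean disc mask of the phantom cross-section
.phantom_disc <- function(design) {
  pc <- .plane_coords(design)
  dx <- pc$x - design$center_offset[1]
  dy <- pc$y - design$center_offset[2]
  sqrt(dx^2 + dy^2) <= design$phantom_diameter / 2
}

# add magnitude (or signed gaussian) noise to a deterministic image
.add_noise <- function(base, sigma, distribution) {
  n <- length(base)
  if (distribution == "rayleigh") {
    g1 <- stats::rnorm(n, 0, sigma)
    g2 <- stats::rnorm(n, 0, sigma)
    matrix(sqrt((base + g1)^2 + g2^2), nrow(base), ncol(base))
  } else {
    base + matrix(stats::rnorm(n, 0, sigma), nrow(base), ncol(base))
  }
}

.image_pair <- function(signal, noise, meta) {
  structure(list(signal = signal, noise = noise, meta = meta),
            class = "image_pair")
}

#' Simulate a combined-element series
#'
#' For each slice: a Signal image (uniform disc of intensity
#' `signal_profile(z)` plus magnitude noise) and a Noise image (noise only).
#' A default 18-slice acquisition therefore produces 36 images.
#'
#' @param design an [acquisition_design()].
#' @param signal_profile function slice location (mm) -> in-slice disc
#'   intensity (a.u., >= 0), e.g. from [coil_signal_profile()].
#' @param noise a [noise_model()].
#' @param seed integer seed; identical seeds give bit-identical pixels.
#' @param filter_label text recorded in the series metadata
#'   (`"unfiltered"` or `"prescan"`).
#' @param series_kind `"combined"` or `"combined_sos"` (metadata only).
#' @return list of `image_pair`s (one per slice, ascending slice location)
#'   with a `truth` attribute: data.frame of slice location, true in-disc
#'   signal and per-channel sigma, plus the design and noise model.
#' @export
make_combined_series <- function(design, signal_profile = NULL,
                                 noise = noise_model(base_sigma = 14,
                                                     central_boost = 1.5),
                                 seed = 1L,
                                 filter_label = "unfiltered",
                                 series_kind = "combined") {
  stopifnot(inherits(design, "acquisition_design"),
            inherits(noise, "noise_model"))
  if (is.null(signal_profile))
    signal_profile <- coil_signal_profile("torso", filter_label)
  z <- slice_positions(design)
  s_true <- vapply(z, signal_profile, numeric(1))
  if (any(s_true < 0)) stop("signal_profile must be >= 0 everywhere")
  disc <- .phantom_disc(design)
  sig <- noise_sigma_at(noise, z)
  pairs <- withr::with_seed(as.integer(seed), {
    lapply(seq_along(z), function(i) {
      base <- disc * s_true[i]
      .image_pair(
        signal = .add_noise(base, sig[i], noise$distribution),
        noise = .add_noise(base * 0, sig[i], noise$distribution),
        meta = list(slice_location = z[i], element = NA_character_,
                    filter_label = filter_label, series_kind = series_kind,
                    pixel_spacing = rep(design$pixel_spacing, 2)))
    })
  })
  attr(pairs, "truth") <- list(
    profile = data.frame(slice_location = z, signal = s_true, sigma = sig),
    design = design, noise = noise, seed = as.integer(seed))
  pairs
}

# deterministic sensitivity image of one element at one slice
.element_base <- function(design, el, z, pc = .plane_coords(design)) {
  r <- design$phantom_diameter / 2
  th <- el$in_plane_angle * pi / 180
  px <- design$center_offset[1] + r * cos(th)
  py <- design$center_offset[2] + r * sin(th)
  d <- sqrt((pc$x - px)^2 + (pc$y - py)^2)
  inplane <- exp(-d / el$inplane_falloff)
  axial <- if (el$fault == "dead") 0.03
           else exp(-((z - el$axial_center) / el$axial_width)^2)
  el$sensitivity_scale * axial * inplane
}

# effective per-channel sigma for an element at a slice
.element_sigma <- function(el, noise, z) {
  boost <- if (abs(z) <= noise$boost_extent) noise$central_boost else 1
  mult <- switch(el$fault, dead = 3, noisy = 1.5, 1)
  el$noise_sigma * boost * mult
}

#' Simulate a "save uncombined" element series
#'
#' Produces one Signal and one Noise image per element and slice (a default
#' 12-element, 18-slice acquisition gives 432 images) plus the combined
#' sum-of-squares by-product series (36 images) whose Signal/Noise images
#' are the root-sum-of-squares over the element images.
#'
#' @param design an [acquisition_design()].
#' @param elements list of [element_model()]s (e.g. [coil_elements()]);
#'   labels must be unique.
#' @param noise a [noise_model()]; its `central_boost`/`boost_extent` apply
#'   on top of each element's own `noise_sigma`, and its `distribution` is
#'   used for the magnitude combination.
#' @param seed integer seed.
#' @return list with `uncombined` (named list: element label -> list of
#'   `image_pair`s), `sos` (list of `image_pair`s of the sum-of-squares
#'   by-product), and a `truth` attribute.
#' @export
make_element_series <- function(design, elements = coil_elements("torso"),
                                noise = noise_model(), seed = 1L) {
  stopifnot(inherits(design, "acquisition_design"), length(elements) >= 1)
  labels <- vapply(elements, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate element labels: ",
                                  paste(labels[duplicated(labels)],
                                        collapse = ", "))
  z <- slice_positions(design)
  disc <- .phantom_disc(design)
  pc <- .plane_coords(design)
  n <- design$matrix

  out <- withr::with_seed(as.integer(seed), {
    unc <- stats::setNames(vector("list", length(elements)), labels)
    sos_sig <- sos_noi <- lapply(seq_along(z), function(i)
      matrix(0, n, n))
    for (k in seq_along(elements)) {
      el <- elements[[k]]
      pairs <- vector("list", length(z))
      for (i in seq_along(z)) {
        base <- disc * .element_base(design, el, z[i], pc = pc)
        sg <- .element_sigma(el, noise, z[i])
        simg <- .add_noise(base, sg, noise$distribution)
        nimg <- .add_noise(base * 0, sg, noise$distribution)
        sos_sig[[i]] <- sos_sig[[i]] + simg^2
        sos_noi[[i]] <- sos_noi[[i]] + nimg^2
        pairs[[i]] <- .image_pair(simg, nimg, meta = list(
          slice_location = z[i], element = el$label,
          filter_label = "unfiltered", series_kind = "uncombined",
          pixel_spacing = rep(design$pixel_spacing, 2)))
      }
      unc[[el$label]] <- pairs
    }
    sos <- lapply(seq_along(z), function(i) .image_pair(
      sqrt(sos_sig[[i]]), sqrt(sos_noi[[i]]), meta = list(
        slice_location = z[i], element = NA_character_,
        filter_label = "unfiltered", series_kind = "combined_sos",
        pixel_spacing = rep(design$pixel_spacing, 2))))
    list(uncombined = unc, sos = sos)
  })
  attr(out, "truth") <- list(
    elements = elements, design = design, noise = noise,
    slice_locations = z, seed = as.integer(seed),
    sigma = vapply(elements, function(el)
      el$noise_sigma * switch(el$fault, dead = 3, noisy = 1.5, 1),
      numeric(1)))
  out
}

#' Write a simulated series to a directory of DICOM files
#'
#' One file per image (`IMG_####.dcm`), Signal before Noise within each
#' slice/element group so InstanceNumber reflects acquisition order, plus a
#' `ground_truth.json` sidecar describing the simulation.
#'
#' @param series result of [make_combined_series()] (a list of
#'   `image_pair`s) or the `uncombined`/`sos` component of
#'   [make_element_series()].
#' @param dir output directory (created if needed).
#' @param series_description label written to every file.
#' @param truth optional list serialised to `ground_truth.json`.
#' @param series_number DICOM series number.
#' @return character vector of written file paths, invisibly.
#' @export
write_series_dicom <- function(series, dir,
                               series_description = "coilqa simulated",
                               truth = attr(series, "truth"),
                               series_number = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pairs <- if (inherits(series[[1]], "image_pair")) series
           else do.call(c, unname(series))
  inst <- 0L
  paths <- character(0)
  for (p in pairs) {
    for (role in c("signal", "noise")) {
      inst <- inst + 1L
      path <- file.path(dir, sprintf("IMG_%04d.dcm", inst))
      dicom_write(p[[role]], path,
                  slice_location = p$meta$slice_location,
                  instance_number = inst,
                  series_description = paste(series_description,
                                             p$meta$series_kind,
                                             p$meta$filter_label),
                  coil_name = if (is.na(p$meta$element)) NA_character_
                              else p$meta$element,
                  pixel_spacing = p$meta$pixel_spacing,
                  series_number = series_number)
      paths <- c(paths, path)
    }
  }
  if (!is.null(truth)) {
    truth_out <- truth
    truth_out$design <- unclass(truth_out$design)
    truth_out$noise <- unclass(truth_out$noise)
    if (!is.null(truth_out$elements))
      truth_out$elements <- lapply(truth_out$elements, unclass)
    jsonlite::write_json(truth_out, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(paths)
}
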