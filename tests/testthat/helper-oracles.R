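# Small fixtures and naive reference implementations used as independent
# oracles.  The oracles are deliberately written as plain double loops /
# exhaustive scans, independent of the package's vectorised code paths.

small_design <- function(matrix = 64L, n_slices = 18L, ...) {
  acquisition_design(matrix = matrix, n_slices = n_slices, ...)
}

# draw a noiseless disc by exhaustive pixel scan
draw_disc <- function(n, center, radius, value = 100, background = 0) {
  img <- matrix(background, n, n)
  for (r in seq_len(n)) for (c in seq_len(n)) {
    if ((r - center[1])^2 + (c - center[2])^2 <= radius^2) img[r, c] <- value
  }
  img
}

# naive sliding-window box mean with replicate borders and top-left-biased
# anchor for even windows
naive_box_mean <- function(img, w) {
  a <- w %/% 2L
  b <- w - 1L - a
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (di in (-a):b) for (dj in (-a):b) {
      ii <- min(max(i + di, 1L), nr)
      jj <- min(max(j + dj, 1L), nc)
      acc <- acc + img[ii, jj]
    }
    out[i, j] <- acc / (w * w)
  }
  out
}

# exhaustive circular-ROI membership scan
naive_roi_members <- function(dim, center, radius) {
  members <- matrix(FALSE, dim[1], dim[2])
  for (r in seq_len(dim[1])) for (c in seq_len(dim[2])) {
    if (sqrt((r - center[1])^2 + (c - center[2])^2) <= radius)
      members[r, c] <- TRUE
  }
  members
}

# naive phantom centre/width: threshold at a fraction of max, bounding box
# by exhaustive scan
naive_center_width <- function(img, fraction = 0.25) {
  th <- fraction * max(img)
  rmin <- Inf; rmax <- -Inf; cmin <- Inf; cmax <- -Inf
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    if (img[r, c] > th) {
      rmin <- min(rmin, r); rmax <- max(rmax, r)
      cmin <- min(cmin, c); cmax <- max(cmax, c)
    }
  }
  list(center = c((rmin + rmax) / 2, (cmin + cmax) / 2),
       width = cmax - cmin + 1, height = rmax - rmin + 1)
}

# hand-built image pair (bypasses the generator)
manual_pair <- function(signal, noise, slice_location = 0,
                        element = NA_character_) {
  structure(list(signal = signal, noise = noise,
                 meta = list(slice_location = slice_location,
                             element = element,
                             filter_label = "unfiltered",
                             series_kind = "combined",
                             pixel_spacing = c(300 / ncol(signal),
                                               300 / ncol(signal)))),
            class = "image_pair")
}
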