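# per-element noise, peak signal, SNR and position derivation

test_that("box smoothing matches a naive sliding-window mean exactly", {
  expect_equal(smooth_signal(matrix(3.7, 20, 20), 10), matrix(3.7, 20, 20))
  # an interior impulse of 100 spreads into a plateau of 1.0 under a 10x10 box
  img <- matrix(0, 30, 30); img[15, 15] <- 100
  sm <- smooth_signal(img, 10)
  expect_equal(max(sm), 1.0)
  expect_equal(sum(sm == 1.0), 100)
  set.seed(51)
  for (w in c(3, 10)) {
    r <- matrix(rnorm(18 * 23), 18, 23)
    expect_equal(smooth_signal(r, w), naive_box_mean(r, w))
  }
})

test_that("peak search erodes the mask and breaks ties lexicographically", {
  img <- matrix(0, 40, 40)
  img[20, 20] <- 5; img[20, 28] <- 5  # two equal maxima after smoothing
  mask <- naive_roi_members(c(40, 40), c(20.5, 20.5), 18)
  pk <- locate_peak_roi(img, mask, roi_radius = 5, window = 1)
  expect_equal(pk$peak_center, c(20, 20))  # smallest (row, col) wins
  # the peak ROI lies entirely inside the phantom mask
  expect_true(all(mask[roi_mask(pk$roi, c(40, 40))]))
  expect_error(locate_peak_roi(img, matrix(FALSE, 40, 40)), "empty")
  tiny <- naive_roi_members(c(40, 40), c(20, 20), 3)
  expect_error(locate_peak_roi(img, tiny, roi_radius = 5), "too small")
})

test_that("the peak ROI targets the element's rim position", {
  d <- small_design(matrix = 96L, n_slices = 5L, slice_thickness = 45,
                    gap_fraction = 0)
  es <- make_element_series(d, list(element_model("VAP1", 0, 90)), seed = 52)
  em <- analyze_element_series(es$uncombined, es$sos)
  row <- em[which.max(em$mean_peak_signal), ]
  # element at 90 degrees (top of the rim): peak well above centre,
  # horizontally centred
  expect_lt(row$peak_row, row$phantom_row - 5)
  expect_equal(row$peak_col, row$phantom_col, tolerance = 6 / row$phantom_col)
  # containment: ROI mean never exceeds the global image maximum
  expect_true(all(em$mean_peak_signal <=
                    sapply(seq_len(nrow(em)), function(i) {
                      lab <- em$element[i]
                      max(sapply(es$uncombined[[lab]], function(p)
                        max(p$signal)))
                    })))
})

test_that("dead and absent elements separate cleanly from healthy ones", {
  d <- small_design(matrix = 64L)
  els <- coil_elements("torso", fault = c(VAS1 = "dead"))[c("VAS1", "VAS2",
                                                            "VAP1")]
  es <- make_element_series(d, els, seed = 53)
  em <- analyze_element_series(es$uncombined, es$sos)
  expect_lt(max(em$snr[em$element == "VAS1"]), 5)
  for (lab in c("VAS2", "VAP1"))
    expect_gt(max(em$snr[em$element == lab]), 20)
  # noise-only channels (physically absent elements): SNR < 3 everywhere
  hn <- make_element_series(d, coil_elements("headneck"), seed = 54)
  emh <- analyze_element_series(hn$uncombined, hn$sos)
  expect_lt(max(emh$snr[emh$element %in% c("VAP3", "VPP3")]), 3)
  expect_lt(max(emh$noise_sd[emh$element == "VAP3"]), 5)
})

test_that("noise SD is computed on identical pixels for all elements of a slice", {
  d <- small_design(matrix = 64L, n_slices = 2L)
  es <- make_element_series(d, coil_elements("torso"), seed = 55)
  # replace every element's Noise image by the same array: identical ROI =>
  # identical SD
  for (lab in names(es$uncombined))
    for (i in seq_along(es$uncombined[[lab]]))
      es$uncombined[[lab]][[i]]$noise <- es$uncombined[[1]][[i]]$noise
  em <- analyze_element_series(es$uncombined, es$sos)
  for (z in unique(em$slice_location))
    expect_equal(length(unique(em$noise_sd[em$slice_location == z])), 1)
})

test_that("with one element the transferred ROI reproduces its own noise SD", {
  d <- small_design(matrix = 96L, n_slices = 2L)
  es <- make_element_series(d, list(element_model("VAP1", 90, 270)), seed = 56)
  em <- analyze_element_series(es$uncombined, es$sos)
  for (i in 1:2) {
    geom <- detect_phantom(es$sos[[i]]$signal)
    roi <- build_combined_roi(geom)
    expect_equal(em$noise_sd[i], sd(roi_pixels(es$uncombined$VAP1[[i]]$noise,
                                               roi)))
  }
})

test_that("peak-SNR summaries use the side-dependent +/-110/130/150 slices", {
  mk <- function(lab, snrs, locs) data.frame(
    element = lab, slice_location = locs, snr = snrs,
    mean_peak_signal = snrs, noise_sd = 1, peak_row = 1, peak_col = 1,
    phantom_row = 1, phantom_col = 1)
  locs <- seq(-170, 170, by = 20)
  snrs <- rep(1, length(locs))
  snrs[match(c(110, 130, 150), locs)] <- c(60, 62, 64)
  s <- summarize_peak_snr(mk("VAP1", snrs, locs))
  expect_equal(s$peak_snr_mean, 62)
  expect_equal(s$peak_snr_sd, 2)
  expect_equal(s$slices_used, "+110/+130/+150")

  snrs2 <- rep(7, length(locs))
  s2 <- summarize_peak_snr(mk("VAS1", snrs2, locs))
  expect_equal(s2$slices_used, "-110/-130/-150")
  expect_equal(s2$peak_snr_mean, 7)
  expect_equal(s2$peak_snr_sd, 0)

  expect_error(summarize_peak_snr(mk("VAP1", 1:3, c(-10, 10, 30))),
               "coverage")
})

test_that("element positions are derived from peak slice sign and rim angle", {
  d <- small_design(matrix = 96L)
  es <- make_element_series(
    d, list(element_model("VAP1", 90, 45), element_model("VAS1", -90, 270)),
    seed = 57)
  em <- analyze_element_series(es$uncombined, es$sos)
  p1 <- derive_element_position(em[em$element == "VAP1", ])
  expect_equal(p1$axial, "superior")
  expect_equal(p1$octant, 2L)  # sector centred on 45 degrees
  p2 <- derive_element_position(em[em$element == "VAS1", ])
  expect_equal(p2$axial, "inferior")
  expect_equal(p2$octant, 7L)  # sector centred on 270 degrees
  # noise-only channel is undetectable (full coil set keeps the
  # sum-of-squares by-product segmentable on every slice)
  hn <- make_element_series(small_design(matrix = 64L),
                            coil_elements("headneck"), seed = 58)
  emh <- analyze_element_series(hn$uncombined, hn$sos)
  expect_equal(
    derive_element_position(emh[emh$element == "VAP3", ])$axial,
    "undetectable")
})

test_that("slice mismatch between series raises an alignment error", {
  d <- small_design(matrix = 96L, n_slices = 2L)
  es <- make_element_series(d, list(element_model("VAP1", 90, 270)), seed = 59)
  expect_error(analyze_element_series(es$uncombined, es$sos[1]),
               "alignment")
})
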