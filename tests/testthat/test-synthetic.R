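# synthetic phantom generator: geometry, noise statistics, faults

test_that("slice centres are symmetric with thickness x (1 + gap) spacing", {
  z <- slice_positions(acquisition_design())
  expect_equal(z, seq(-170, 170, by = 20))
  expect_equal(max(z) - min(z), 340)   # +/- 17 cm of axial coverage

  expect_equal(slice_positions(acquisition_design(n_slices = 1)), 0)
  expect_equal(
    slice_positions(acquisition_design(n_slices = 4, slice_thickness = 5,
                                       gap_fraction = 0)),
    c(-7.5, -2.5, 2.5, 7.5))
})

test_that("invalid designs are rejected", {
  expect_error(acquisition_design(n_slices = 0), "n_slices")
  expect_error(acquisition_design(slice_thickness = -1), "slice_thickness")
  expect_error(acquisition_design(matrix = 8), "matrix")
})

test_that("a combined series yields one Signal and one Noise image per slice", {
  ser <- make_combined_series(small_design(n_slices = 18L), seed = 1)
  expect_length(ser, 18)
  td <- withr::local_tempdir()
  write_series_dicom(ser, td)
  expect_length(list.files(td, pattern = "\\.dcm$"), 36)
  expect_true(file.exists(file.path(td, "ground_truth.json")))
})

test_that("identical seeds give bit-identical pixels, different seeds differ", {
  d <- small_design(matrix = 32L, n_slices = 2L)
  a <- make_combined_series(d, seed = 42)
  b <- make_combined_series(d, seed = 42)
  c3 <- make_combined_series(d, seed = 43)
  expect_identical(a[[1]]$signal, b[[1]]$signal)
  expect_identical(a[[2]]$noise, b[[2]]$noise)
  expect_false(identical(a[[1]]$signal, c3[[1]]$signal))
})

test_that("magnitude images are nonnegative everywhere", {
  ser <- make_combined_series(small_design(matrix = 32L, n_slices = 3L),
                              seed = 5)
  for (p in ser) {
    expect_gte(min(p$signal), 0)
    expect_gte(min(p$noise), 0)
  }
  es <- make_element_series(small_design(matrix = 32L, n_slices = 2L),
                            coil_elements("torso"), seed = 5)
  expect_gte(min(sapply(es$uncombined, function(ps)
    min(sapply(ps, function(p) min(p$signal, p$noise))))), 0)
})

test_that("gaussian-mode Noise-image ROI SD recovers the generator sigma", {
  # large disc: relative tolerance 3 / sqrt(2 N) around sigma
  sigma <- 12
  d <- small_design(matrix = 128L, n_slices = 1L)
  ser <- make_combined_series(
    d, signal_profile = function(z) 400,
    noise = noise_model(base_sigma = sigma, central_boost = 1,
                        distribution = "gaussian"),
    seed = 17)
  geom <- detect_phantom(ser[[1]]$signal)
  roi <- build_combined_roi(geom)
  nv <- roi_pixels(ser[[1]]$noise, roi)
  expect_equal(sd(nv), sigma, tolerance = 3 / sqrt(2 * length(nv)))
})

test_that("with a zero signal profile, Signal and Noise are statistically alike", {
  d <- small_design(matrix = 64L, n_slices = 2L)
  ser <- make_combined_series(d, signal_profile = function(z) 0, seed = 9)
  for (p in ser) {
    expect_equal(mean(p$signal), mean(p$noise), tolerance = 0.05)
    expect_equal(sd(p$signal), sd(p$noise), tolerance = 0.05)
  }
})

test_that("an element series has 2 images per element and slice plus the by-product", {
  d <- small_design(matrix = 32L, n_slices = 3L)
  es <- make_element_series(d, coil_elements("torso"), seed = 2)
  expect_length(es$uncombined, 12)
  expect_true(all(lengths(es$uncombined) == 3))
  expect_length(es$sos, 3)
  td <- withr::local_tempdir()
  write_series_dicom(es$uncombined, td)
  expect_length(list.files(td, pattern = "\\.dcm$"), 12 * 3 * 2)
})

test_that("duplicate element labels are rejected", {
  d <- small_design(matrix = 32L, n_slices = 1L)
  els <- list(element_model("VAP1", 90, 270), element_model("VAP1", 90, 90))
  expect_error(make_element_series(d, els), "duplicate")
})

test_that("a dead element has a flat signal response and ~3x noise", {
  d <- small_design(matrix = 48L, n_slices = 6L)
  es <- make_element_series(
    d, coil_elements("torso", fault = c(VAS1 = "dead")), seed = 8)
  tr <- attr(es, "truth")
  expect_equal(tr$sigma[["VAS1"]], 3 * tr$sigma[["VAS2"]])
  # flat response: the dead element's measured signal (noise-floor
  # dominated) varies far less across slices than a healthy element's
  disc_mean <- function(ps) sapply(ps, function(p) mean(p$signal))
  rel_range <- function(x) diff(range(x)) / mean(x)
  dead <- rel_range(disc_mean(es$uncombined$VAS1))
  healthy <- rel_range(disc_mean(es$uncombined$VAS2))
  expect_lt(dead, 0.6)
  expect_gt(healthy, 2 * dead)
})

test_that("with one element the sum-of-squares by-product is that element", {
  d <- small_design(matrix = 32L, n_slices = 2L)
  es <- make_element_series(d, list(element_model("VAP1", 90, 270)), seed = 4)
  for (i in 1:2) {
    expect_equal(es$sos[[i]]$signal, es$uncombined$VAP1[[i]]$signal)
    expect_equal(es$sos[[i]]$noise, es$uncombined$VAP1[[i]]$noise)
  }
})
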