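---
title: "Receive-coil QA from multi-slice phantom images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Receive-coil QA from multi-slice phantom images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coilqa)
```

## The measurement problem

Phased-array receive coils on MR-guided radiotherapy systems degrade with
wear: individual receiver elements die outright or slowly record more noise
and less signal. Because the clinical image combines all elements, a single
degraded element shows up only as a diffuse loss of signal-to-noise ratio
(SNR) or uniformity. The QA procedure this package automates images a long
cylindrical phantom with a spin-echo sequence twice per slice — once
normally ("Signal" image) and once with the RF transmitter off ("Noise"
image) — over a stack of axial slices spanning the phantom, for three
series kinds: combined-element images without and with prescan
normalization, and per-element "save uncombined" images together with
their sum-of-squares combined by-product.

`coilqa` takes directories of such DICOM images and computes, per slice:

* **SNR** = *c* · mean(Signal ROI) / SD(Noise ROI), with the ROI a circle
  at the detected phantom centre whose diameter is 90% of the phantom
  width. The correction *c* defaults to 1 (the plain ratio of the two ROI
  statistics); `c = 0.655` can be selected to convert the Rayleigh-distributed
  magnitude-noise SD into the underlying per-channel noise sigma. The
  choice rescales every value, so it must be held constant across a
  longitudinal series; the default is the plain ratio because that is the
  construction the QA workflow traces.
* **Percent image uniformity (PIU)** = 100 (1 − (S\_max − S\_min) /
  (S\_max + S\_min)) over the Signal ROI extremes.

For uncombined series, per element and slice: the noise SD inside the
circular ROI *transferred from the sum-of-squares combined series* (so all
elements of a slice are measured on identical pixels), and the mean signal
in a 5-px-radius ROI (5.86 mm at FOV 300 mm / matrix 256) centred on the
intensity peak of the 10-px box-smoothed Signal image. Per element, the
SNR of the three slices where element SNR peaks (±110/130/150 mm,
superior for groups whose third letter is P, inferior for S) is averaged
into a longitudinal summary statistic.

## Segmentation and numerical choices

* Threshold: Otsu's method on the full image (scale invariant), with a
  fraction-of-maximum alternative. Holes are filled and the largest
  connected component kept, which makes detection robust to in-plane
  intensity dips.
* "Phantom width" is the horizontal extent of the component; the centre is
  the midpoint of the horizontal and vertical extents. Coordinates are
  1-based (row, col) with pixel centres at integer positions — the natural
  convention for R matrices — and circle membership is decided by
  pixel-centre Euclidean distance.
* The box filter uses replicate borders; for the even 10-px window the
  anchor is biased toward the top-left (output *i* averages rows
  *i*−5 … *i*+4). It is implemented with padded integral images and matches
  a naive sliding-window mean exactly.
* The peak search runs on the smoothed image restricted to the phantom
  mask eroded by the peak-ROI radius. Smoothing alone usually keeps the
  peak away from the rim, but the erosion *guarantees* the ROI sits inside
  the phantom for any input. Ties are broken toward the smallest
  (row, col).
* Signal/Noise classification uses the larger image maximum; exact ties
  fall back to acquisition order (lower InstanceNumber = Signal). Slice
  locations are rounded to 0.1 mm for grouping.

## Pass/warn/fail baselines

Each coil set and condition keeps an append-only history. A new value
warns beyond 2 sample SDs of the accepted history mean and fails beyond 3;
the alternative percent criterion warns at 5% and fails at 10% of the
mean, and `"auto"` selects percent for baselines shorter than 10 entries.
Thresholds are two-sided: the documented failures are drops, but a flare
(e.g. a uniformity increase from a dying element's missing shading) is
equally suspicious. Failed measurements are stored but flagged
not-accepted, so they never contaminate later baselines; warn-level
measurements are accepted by default (overridable), since excluding them
would bias baselines toward stability.

The overall verdict for a measurement is a documented configuration, not a
published prescription: any failing element fails the run; for combined
series a metric fails the run when more than half of its slices fail,
while a minority of failing slices yields a warning.

With a 10-point baseline the 2-SD rule has only ≈91% per-metric coverage
(the sample mean and SD are themselves noisy — a *t*-distribution effect),
so short-baseline evaluations should use the percent criterion; that is
exactly why the alternative exists.

## The synthetic acquisition generator

The generator is first-class, tested code: it defines the study conditions
under which the estimators are validated.

* **Geometry**: 18 axial slices, 10 mm thick, 100% gap (centres −170 …
  +170 mm, i.e. ±17 cm), FOV 300 mm, matrix 256, phantom diameter 135 mm.
* **Noise**: per-channel Gaussian sigma with a ×1.5 step boost inside
  ±30 mm of isocenter (the split-magnet design elevates noise on the four
  central slices). The default magnitude model is Rayleigh/Rician (two
  i.i.d. quadrature channels), which keeps all pixels nonnegative; a
  signed pure-Gaussian mode exists for analytically exact estimator tests
  (there the noise-ROI SD equals sigma exactly). Gaussian-mode images are
  signed and are persisted to DICOM via a negative RescaleIntercept.
* **Combined signal**: a uniform in-slice disc whose intensity follows an
  axial profile; the default torso profile is a 680 a.u. lobe at +90 mm
  plus a 430 a.u. lobe at −90 mm (head/neck mirrored; prescan and body
  profiles are single bells centred at isocenter). Peak intensities and
  the +90/−90 mm peak locations follow the instrument's documented
  behaviour.
* **Elements**: separable sensitivity — exponential in-plane falloff
  (decay length 60 mm) from a point on the phantom rim at the element's
  angle, times a Gaussian axial falloff (width 75 mm) centred at ±90 mm.
  Twelve channels in four groups of three; for head/neck coils the VAP3
  and VPP3 channels are physically absent and modelled as zero sensitivity
  with low receiver noise (≈1.5 a.u. sigma), reproducing their
  characteristic SNR < 3 signature. Element noise sigma defaults to
  10 a.u., giving central noise-ROI SDs near 10 a.u. and healthy peak-SNR
  summaries in the 40–55 range.
* **Faults**: `dead` = flat residual signal (3% of scale, no axial
  dependence) with ×3 noise — its summary SNR lands near 2, matching the
  documented dead-element case; `noisy` = ×1.5 noise with unchanged
  signal, a ≈20–30% SNR reduction.

### What the generator does *not* emulate

In-plane signal shading of combined images (the disc is uniform per
slice), so synthetic unfiltered PIU is higher (≈90%) than the ≈75% typical
of real unfiltered surface-coil images and prescan normalization changes
only the axial profile; graded noise falloff toward the FOV edge (the
step model cannot shift the SNR maximum from the signal peak at ±90 mm out
to ±130 mm as real data show); reconstruction, ghosting, distortion and
motion. Passing tests therefore validate the estimators and decision
logic, not scanner physics.

## Problem sizes

The default design (matrix 256) is used for the series-structure checks;
estimator-recovery runs use matrix 96 over 50–100 seeds and the
fault-detection study matrix 128 with a 10-run baseline and 20–50
evaluation seeds — sizes at which the measured quantities are stable (peak
SNR summaries scatter by ≲1.5% across seeds) while the full suite runs in
minutes.

## DICOM handling

Files are classic single-frame MR Image Storage in explicit-VR
little-endian, written and read by a small codec covering the attributes
the analysis needs (slice location — SliceLocation with
ImagePositionPatient[3] fallback — Receive Coil Name for the element
label, SeriesDescription for the series/filter condition, InstanceNumber
as the acquisition-order proxy, PixelSpacing, rescale). Pixels are stored
as 16-bit unsigned integers; the codec is cross-checked against an
independent Python DICOM reader in the test suite. Axial orientation is
assumed and images are used in stored row/column order; multiframe and
compressed transfer syntaxes are out of scope.

## Known limitations

* The in-plane element sensitivity shape is qualitative: only the peak
  locations are constrained by the instrument documentation, so derived
  octants are coarse by construction.
* Segmentation is per slice; a per-series consensus geometry would be
  slightly more robust at very low SNR but could hide slice-dependent
  failures.
* The "video" deliverable is a numbered PNG frame sequence per element;
  no MP4 assembly is performed.
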