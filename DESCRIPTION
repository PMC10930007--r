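Package: coilqa
Title: Automated Quality Assurance for MR Receive Coils from Multi-Slice
    Phantom Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated signal-to-noise ratio (SNR) and percent image
    uniformity (PIU) analysis of multi-slice spin-echo phantom acquisitions
    used for receive-coil quality assurance on low-field MR-guided
    radiotherapy systems.  Reads paired Signal (RF on) and Noise (RF off)
    DICOM series, segments the phantom, computes NEMA-style per-slice SNR
    and uniformity for combined-element images, per-element noise, peak
    signal and SNR profiles for "save uncombined" series, and renders
    longitudinal pass/warn/fail decisions against stored baselines.  A
    synthetic phantom-acquisition generator with known ground truth and
    injectable coil-element faults makes the whole pipeline testable
    without a scanner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ggplot2,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    withr
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
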