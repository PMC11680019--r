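Package: ppghemo
Title: Peripheral Hemodynamic Features from Multi-Wavelength Photoplethysmograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline for dual-wavelength (green / near-infrared)
    finger photoplethysmograms aimed at peripheral (arteriole and capillary)
    hemodynamics. Implements zero-phase band-pass filtering, velocity and
    acceleration plethysmograms, beat segmentation, per-beat fiducial detection
    (PPG minima/maximum, VPG maximum, APG a-e waves), the 1/FWHM family of
    rise-steepness features, the green-versus-near-infrared a-wave peak delay,
    template-subtraction signal-to-noise quality control with strict exclusion
    rules, group summaries and Welch comparisons, a Bramwell-Hill pulse wave
    velocity helper, and a calibrated dual-channel synthetic PPG simulator with
    per-beat ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
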