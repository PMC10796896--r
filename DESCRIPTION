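Package: bilistrip
Title: Smartphone Colorimetry of Bilirubin Test Papers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of direct-bilirubin test papers photographed
    under narrow-band LED illumination. Provides a spectral forward model (LED
    emission lines, concentration-dependent stained-paper reflectance, CIE 1931
    chromaticity, camera RGB formation), region-of-interest image statistics
    with the YUV luminance transform, linear calibration fitting with 3-sigma
    detection and 10-sigma quantification limits and inverse prediction, a
    seeded synthetic test-paper image generator, and an end-to-end analysis
    pipeline comparing light sources and colour channels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
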