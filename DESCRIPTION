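Package: neotherm
Title: Camera Fusion for Neonatal Skin-Temperature Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fusing RGB and infrared-thermography (IRT) recordings of
    neonates to monitor skin temperature without skin contact. The package
    registers the two modalities by maximizing mutual information over an
    affine transform plus a field-of-view crop, transfers COCO-style body
    keypoints from the RGB frame into thermal coordinates, extracts
    region-of-interest temperatures at each landmark, and computes the
    central-peripheral temperature difference (cpTD), a clinical marker
    relevant to neonatal sepsis screening. A synthetic-phantom generator with
    fully known geometry and temperature field supports end-to-end validation,
    including OKS-based average precision, point-transformation error, cpTD
    error statistics, and Bland-Altman agreement analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lhs,
    png,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
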