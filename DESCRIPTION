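Package: fluoroscan
Title: High-Throughput Crop Physiology Monitoring from Chlorophyll
    Fluorescence and Multispectral Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pulse-amplitude-modulated (PAM) chlorophyll fluorescence
    and multispectral imaging of greenhouse crops. Computes per-pixel maps and
    per-plant summaries of the maximum PSII quantum efficiency (Fv/Fm), the
    operating PSII quantum efficiency (PhiPSII) and the 550/510 relative
    reflectance ratio from six-frame acquisition stacks; segments plants from
    background by fluorescence thresholding or two-class k-means on the
    multispectral frames; classifies drought, nitrogen deficiency and
    Botrytis-type disease from indicator trajectories with a transparent rule
    table; and provides calibrations linking PhiPSII to leaf water potential
    and Fv/Fm to total nitrogen content (including the Nessler standard-curve
    computation). A seeded synthetic scene generator emulates the imaging
    instrument so the whole pipeline is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    EBImage
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
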