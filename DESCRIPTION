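Package: adiposcore
Title: Per-Nucleus Lipid Droplet Scoring for Adipogenesis Image Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies adipocyte differentiation from two-channel
    fluorescence microscopy (Hoechst/DAPI nuclei plus Nile Red lipid
    droplets) or RGB Oil Red O / haematoxylin images. Implements local
    Gaussian-mean adaptive thresholding robust to heavy and spatially
    varying background staining, watershed separation of touching nuclei,
    size and shape filters that exclude dead cells and saturated
    multilayer clumps, a per-nucleus lipid score (foreground-area fraction
    times stain intensity in the nucleus neighbourhood), per-well
    adipogenic scores with histograms, droplet sizing by circular Hough
    transform, and a fully ground-truthed synthetic scene generator for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
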