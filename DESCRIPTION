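Package: wheatspike
Title: Texture-Based Wheat Spike Segmentation and Heading-Time Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects wheat spikes (ears) in side-view RGB images of single
    potted plants and derives heading time point (HTP) and spike-area growth
    curves from daily multi-orientation image series. The detector combines
    colour-index plant segmentation (2g - r - b), a single-level Haar wavelet
    decomposition, Laws texture-energy features classified per pixel by a
    small 8-10-2 feed-forward network, multi-scale Frangi vesselness to
    suppress leaf-crossing artefacts, and morphological spike reconstruction.
    A parametric scene simulator with ground-truth masks supports training
    and end-to-end evaluation without glasshouse imagery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    nnet,
    igraph,
    png,
    tiff,
    jpeg,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
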