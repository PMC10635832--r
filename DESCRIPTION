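Package: xistquant
Title: Quantification of Xist RNA-FISH, Nuclear Translocation and
    Flow-FISH Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated analysis of RNA-FISH and immunofluorescence
    microscopy of X-chromosome inactivation experiments. Provides
    nucleus segmentation (Gaussian smoothing, Otsu thresholding,
    dilation and distance-transform watershed) with area and
    circularity filtering, ring-based nuclear-to-cytoplasmic ratio
    estimation for transcription-factor translocation, Xist RNA cloud
    detection and summed-intensity scoring, Huwe1 nascent-transcript
    counting for embryo sexing, Flow-FISH percentile gating with
    background-corrected geometric means, qPCR dosage-ratio
    classification of transgene boundaries, the associated rank-sum and
    t statistics with Benjamini-Hochberg correction, and a seeded
    synthetic-data generator with full ground truth for parameter
    recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    stats,
    tiff,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
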