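Package: mitomorph
Title: Quantitative Mitochondrial Morphometry from Transmission Electron Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reproducible quantification of mitochondrial morphology in
    transmission electron micrographs. Implements a semi-automated
    segmentation chain (image inversion, rolling-ball background
    subtraction, FFT bandpass filtering with directional stripe
    suppression, maximum-entropy thresholding), region-of-interest
    restricted particle analysis yielding eight shape parameters (area,
    squared area, perimeter, major and minor axis, Feret's diameter,
    circularity, roundness, aspect ratio, form factor), per-cell
    aggregation, and many-to-one group statistics (one-way ANOVA with
    Dunnett's test, Fisher's LSD, Shapiro-Wilk screening). A synthetic
    micrograph generator with analytic ground truth and a qPCR
    triplicate-QC plus relative-expression (2^-ddCt) module support
    end-to-end validation without external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    multcomp,
    mvtnorm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
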