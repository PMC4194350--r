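Package: excretaScan
Title: Quantitative Analysis of Dye-Labelled Faecal Deposits in Drosophila Plate Scans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects dye-stained faecal deposits in high-resolution scans of
    clear plastic plates, quantifies their size, shape and colour, and turns
    them into per-plate physiological readouts for Drosophila excretion
    assays. Deposits are segmented by adaptive (local-mean) thresholding with
    8-connected component labelling and hole filling, then described by the
    standard graphical variables: area, contour perimeter, circularity
    (4*pi*area/perimeter^2), reproductive-oblong-deposit (ROD) classification
    by a circularity cutoff, integrated optical density (area * (1 - mean
    Lightness)) and mean colour in the RGB and HSL models. Plate-level
    summaries (normalised per fly, overall and for ROD/non-ROD subsets) feed
    group comparisons by Student's t or Mann-Whitney U tests with Jarque-Bera
    normality guidance and Holm-Bonferroni correction. A seeded synthetic
    plate generator with per-spot ground truth supports validation, and a
    batch processor provides annotated images, CSV exports and an audit
    trail.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    tiff,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
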