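Package: cleaf
Title: Label-Free Confocal Laser Endomicroscopy Autofluorescence Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of label-free confocal laser
    endomicroscopy (CLE) autofluorescence frames of brain tissue: a synthetic
    frame generator with ground-truth annotations and paired bandpass/longpass
    acquisitions, automated quality-control exclusion flags (no discernible
    signal, motion artifact, duplicated field of view), line-profile
    signal-to-noise estimation with an exact paired Wilcoxon signed-rank
    comparison of detection filters, detection and classification of nine
    autofluorescence features (punctuate signals, fluorescent-cytoplasm cells,
    diffuse autofluorescence, fibers, round homogeneous structures), per-case
    abundance aggregation and Chernoff-face glyph reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    fftwtools,
    Rcpp,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
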