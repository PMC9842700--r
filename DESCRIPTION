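Package: imagetx
Title: Imaging Transcriptomics of fMRI-Defined Cortical Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end imaging-transcriptomics pipeline that
    characterizes fMRI-defined brain regions by their anatomical
    gene-expression signatures, using Allen Human Brain Atlas (AHBA) style
    per-donor microarray bundles. Implements detection-rate and RNA-seq
    concordance probe selection, hemisphere mirroring and trilinear mask
    sampling of MNI sample coordinates, donor batch removal with two-pass
    scaled robust sigmoid normalization, empirical-Bayes moderated
    differential expression with a consensus intra-donor correlation,
    differential-stability quality control, and hypergeometric gene-set and
    cell-type marker enrichment. Ships a seed-deterministic synthetic atlas
    generator with planted ground truth so the whole pipeline can be
    validated without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
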