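Package: spicefuse
Title: Chemometric Species Classification of Zingiberaceae Spices by
    Multi-Spectral Data Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for discriminating Zingiberaceae spice species from
    volatile-metabolite profiles and vibrational spectra. Implements NIPALS
    partial least squares discriminant analysis (PLS-DA), orthogonal PLS-DA,
    principal component analysis, variable importance in projection (VIP)
    screening, Kennard-Stone calibration/validation partitioning, three
    NIR+MIR multi-block data-fusion strategies (low-level concatenation,
    mid-level VIP feature selection, mid-level latent-variable scores),
    permutation-test model validation, and hierarchical-clustering summaries
    of metabolite tables. Ships a synthetic-data generator that emulates the
    13-species x 15-sample study design from published per-species
    metabolite means and standard deviations, so the full workflow is
    reproducible without the original instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr,
    jsonlite
Config/testthat/edition: 3
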