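Package: ctpls
Title: Imaging Transcriptomics of Cortical Thickness Differences via Partial Least Squares
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links regional case-control differences in cortical thickness to
    regional gene expression with partial least squares regression (PLSR).
    Provides scanner-site-adjusted thickness difference maps, cross-validated
    component selection, permutation tests of explained variance, bootstrap
    z-scoring of gene weights with FDR inverse quantile transformation to
    counter winner's-curse bias, spatial characterization of significant genes
    across Von Economo cytoarchitectonic classes with permutation nulls, and
    gene-length-adjusted logistic gene-set enrichment.  Includes a synthetic
    data generator with planted ground truth so the full pipeline is testable
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
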