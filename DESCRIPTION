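Package: selandscape
Title: Superenhancer Landscape Mapping and Tumor-Specific Dependency Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps the active cis-regulatory landscape of tumor and normal
    samples from H3K27Ac ChIP-seq peak calls and coverage. Implements
    ROSE-style enhancer stitching and rank-inflection superenhancer (SE)
    classification per sample, cross-sample consensus enhancer/SE maps with
    fixed-width binning, input-subtracted RPKM scoring and SE presence
    calls, variance-based sample clustering, SE-to-gene association by
    expression correlation within a cis window, tumor-specific SE
    identification (acquired and enlarged modes), and CRISPR dropout screen
    scoring with control-anchored normalization, hit calling, and
    dependency-correlated SE signatures. Ships a synthetic-study generator
    with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    cluster,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
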