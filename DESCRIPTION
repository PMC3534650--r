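Package: ccam
Title: Canonical Correspondence Analysis for Paired Transcriptome Datasets
Version: 0.1.0
Authors@R:
    person("CCAM", "Maintainers", email = "ccam@example.org", role = c("aut", "cre"))
Description: Constrained ordination of a gene-by-sample expression matrix
    (e.g. disease transcriptomes) on per-population averaged profiles from a
    second, independent dataset (e.g. sorted normal cell populations).
    Implements the chi-square-metric standardization, weighted projection
    onto the explanatory (environmental) profiles, singular value
    decomposition, gene/sample/environment score systems and inertia
    decomposition of canonical correspondence analysis, together with
    moderated-t gene signatures, axis-derived prognostic scoring with
    percentile stratification, Kaplan-Meier/log-rank/Cox survival analysis,
    a synthetic-data generator with known ground truth, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    survival,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    vegan
Config/testthat/edition: 3
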