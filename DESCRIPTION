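Package: megapath
Title: Multi-Cohort Expression Mega-Analysis with Pathway Enrichment and
    Shared-Pathway Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pools per-study log2 fold-changes from multiple case/control
    gene-expression cohorts under fixed- and random-effects models
    (DerSimonian-Laird), with Cochran's Q / I-squared heterogeneity
    diagnostics and heterogeneity-driven model selection. Classifies
    literature-derived regulator-target relations against disease
    direction, regresses per-study effects on study-level covariates,
    performs Fisher's exact gene-set enrichment with
    Benjamini-Hochberg FDR control and Jaccard similarity, and builds
    shared-pathway interaction networks. Includes a synthetic-data
    generator with recorded ground truth so every stage of the
    pipeline is testable without access to the original cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite
Config/testthat/edition: 3
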