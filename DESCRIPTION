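Package: protraj
Title: Subphenotyping of Repeatedly Measured Proteomic Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives patient subphenotypes from longitudinal aptamer-based
    proteomic profiles. Per-protein linear mixed-effects models turn repeated
    standardized measurements into per-patient trajectory features (predicted
    intercepts and slopes), which are embedded, clustered by k-means with the
    number of clusters chosen by a bootstrap consensus over an ensemble of
    cluster-validity indices, and checked for stability under random noise via
    Jaccard similarity. Protein subsets driving the allocation are identified
    by clustering proteins and testing per-protein association
    (Kruskal-Wallis with Benjamini-Hochberg correction), and subphenotypes are
    related to time-to-event outcomes through Cox proportional-hazards models
    with optimism-corrected concordance. A synthetic-cohort generator with
    known subphenotype structure makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    survival
Suggests:
    testthat (>= 3.0.0),
    lme4,
    mclust,
    cluster
Config/testthat/edition: 3
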