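Package: microdepth
Title: Depth- and Time-Structured Soil Microbiome Community Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream statistical analysis of depth- and time-structured soil
    prokaryotic amplicon sequence variant (ASV) count tables: rarefaction,
    rare/abundant partitioning and layer-enrichment classification, alpha
    diversity with balanced two-way ANOVA and Tukey post-hoc tests, a soil
    fertility index with permutation-calibrated random-forest driver analysis,
    Bray-Curtis ordination (PCoA), PERMANOVA and Mantel tests implemented from
    first principles, rule-based functional-group mapping, and co-occurrence
    networks with Zi-Pi module-role keystone classification.  Includes a
    synthetic-data generator that emulates a plots-by-times-by-depths sampling
    design so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    randomForest,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    yaml,
    optparse
Config/testthat/edition: 3
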