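Package: lungmir
Title: miRNA Expression Profiling and Multi-miRNA Target Prioritization in
    Allergic Airways Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for microRNA microarray profiling in a
    steroid-sensitive murine model of allergic airways disease: percentile-shift
    normalization, group-level detection calling, signed fold changes with exact
    Mann-Whitney testing over a four-group (PBS/PBS, PBS/OVA, OVA/OVA,
    OVA/OVA DEX) design, steroid-sensitivity and Venn classification of
    differentially expressed miRNAs, hierarchical clustering of expression
    profiles, combinatorial prioritization of genes targeted by multiple
    differentially expressed miRNAs, and qPCR relative quantification
    (2^-dCt) with array-vs-qPCR concordance. Includes seeded synthetic-data
    generators with planted ground truth so every stage is testable without
    the original arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
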