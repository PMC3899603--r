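Package: leptinprog
Title: Factorial Analysis of Transcriptional Programming by Maternal Diet
    and Neonatal Leptin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies transcriptional programming in a
    balanced 2x2x2 factorial rodent study (maternal diet x neonatal leptin
    treatment x postweaning diet). Implements the full analytic chain:
    per-cell outlier exclusion and detection-call presence filtering,
    one-way ANOVA gene selection with Benjamini-Hochberg false discovery
    rate control, three-way factorial ANOVA with iterative non-confounded
    category assignment, classification of maternal-diet-by-leptin
    interactions into reversal, synergistic and partially opposing types,
    hierarchical clustering of diet-corrected residual expression profiles,
    a three-filter biomarker cascade with precursor flagging, and
    three-factor analyses of endpoint phenotypes and longitudinal growth.
    A synthetic-data generator with known ground truth makes every stage
    testable without microarray data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    yaml,
    ape,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
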