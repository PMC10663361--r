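Package: primescan
Title: Classification of Primed Enhancer Elements Across Developmental
    Stage Transitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies "primed" cis-regulatory elements -- open-chromatin
    regions with reporter-assayed enhancer activity whose linked gene is
    not yet expressed but is significantly up-regulated at the next
    developmental stage.  Implements the enhancer-screen fragment
    filtering cascade and High/Low activity-state assignment, distal
    peak-to-gene linking via promoter-capture Hi-C with nearest-gene
    fallback, the CPM/differential-expression priming gate, PWM log-odds
    motif scanning, construction and export of motif-based priming gene
    regulatory networks, primed-versus-active enhancer feature
    comparison, eRNA summaries and VEGF-responsiveness classification.
    Ships a seeded synthetic-data generator with ground truth so the
    whole pipeline runs and validates without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
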