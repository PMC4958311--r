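Package: oncofunnel
Title: Cross-Species Copy-Number Driver Discovery for Murine Mammary Tumor Subtypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative oncogenomic driver discovery in murine
    mammary tumor models. Implements a two-class SAM (Significance Analysis of
    Microarrays) statistic with permutation-based false discovery rate
    calibration, array-CGH probe filtering and ten-probe windowed smoothing,
    class-specific copy-number region calling, DNA-RNA cis-correlation
    filtering, gene-level thresholded copy-number calls from human
    segmentation data with basal-like enrichment testing, a rank-based shRNA
    dropout essentiality score with a permutation null, and the
    candidate-drug-target filtering funnel that combines all of these into
    per-subtype driver candidates. A synthetic multi-omic cohort generator
    with planted drivers, passengers and class signatures provides ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests: testthat (>= 3.0.0), withr, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
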