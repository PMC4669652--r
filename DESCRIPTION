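Package: chipcoloc
Title: Co-Localization, Annotation, Motif Enrichment and QC for ChIP-Seq Peak Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of ChIP-seq peak sets: pairwise peak
    co-localization under the at-least-1-bp overlap rule with Fisher's exact
    and permutation statistics, distance-to-TSS and promoter-fraction
    profiling, single-nearest-gene assignment within a 50 kb extension,
    known-motif enrichment in summit windows against GC-matched random
    background with exact PWM score-threshold calibration and a one-sided
    binomial test, and ENCODE-style quality metrics (SPOT, PBC, strand
    cross-correlation NSC/RSC, saturation analysis). A synthetic-data
    generator with recorded ground truth emulates every input the analyses
    consume, so the whole pipeline runs with no external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
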