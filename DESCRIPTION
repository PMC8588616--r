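Package: loopwise
Title: Chromatin-Loop Dysregulation Analysis with Sliding-Window Genomic Nulls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies CTCF-anchored chromatin loops by differential
    boundary-peak status between two conditions and scores coordinated
    loop-wide expression changes against a sliding-window genomic null with a
    percentile representation and Beta Q-Q diagnostics. Includes supporting
    stages for single-cell ATAC cell quality control, peak-to-gene assignment,
    ligand-receptor pairing between cell populations, and transposase cut-site
    meta-profiles around reference sites, together with a seeded synthetic-data
    generator (negative-binomial single-cell counts with loop-coordinated fold
    changes, condition-specific anchor-peak loss, and motif-centered fragment
    pile-ups) so the full analysis runs end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    yaml,
    S4Vectors,
    GenomeInfoDb,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
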