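Package: gcskew
Title: GC Skew Index for Bacterial Genome Assembly Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the replication-associated GC skew of bacterial
    chromosomes as a single normalized skew index (SkewI) between 0 and 1,
    computed from window-level G/C polarity over a circularized genome with a
    flexible leading/lagging-strand transition point. Provides genus-level
    cohort statistics with outlier thresholds (mean minus two standard
    deviations) to flag potentially mis-assembled genomes, rearrangement
    operators (translocation, segment inversion) with a detection-sensitivity
    simulation, a parameterized synthetic-genome generator for testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
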