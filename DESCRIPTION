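Package: znetdiff
Title: Label-Free Proteomics Differential Expression with Znet Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential protein expression analysis for label-free,
    two-condition by two-replicate proteomics experiments quantified by
    total ion count (TIC). Peptide-level fragment intensities are rolled up
    to protein TIC values, cross-state and intra-replicate log2-ratio
    populations are normalized and merged into a single Znet score per
    protein with tiered significance cutoffs, and a per-protein
    signal-to-noise statistic is calibrated against a Monte-Carlo
    permutation null to relate signal-to-noise cutoffs to false discovery
    rates. Includes a synthetic-data generator with known ground truth,
    COG-class cross-tabulation and three-way overlap summaries, and a
    deterministic config-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
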