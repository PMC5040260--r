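Package: sdpensemble
Title: Group-Specific Specificity-Determining-Position Scoring over
    Sub-Sampled Alignment Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies specificity determining positions (SDPs) in protein
    families whose members are partitioned into ortholog sets (specificity
    groups). Rather than scoring a single multiple sequence alignment, the
    package sub-samples the sequence pool under per-group allocation
    constraints, aligns each sub-sample together with a reference sequence,
    scores every alignment column with an identity-matrix GroupSim-style
    statistic extended to group-specific scores with degenerate-group noise
    filtering, and aggregates scores across the alignment ensemble by
    reference position. Includes a synthetic sequence-pool simulator with
    planted column archetypes for validation, pool curation by pairwise
    identity, conservation-agreement projections, heterogeneity
    classification, and percentile-based SDP calls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
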