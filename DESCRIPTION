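Package: flucres
Title: Fluctuating Amino Acid Residues: Classification, Profiling and
    Rank-Occupancy Analysis of Protein Sequences
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies the 20 standard amino acids into high, moderate
    and weak fluctuating groups and scores protein sequences with the
    corresponding integer fluctuation index (-2/-1/+2). Provides
    per-residue fluctuation profiles with optional smoothing, class
    composition summaries over sequence sets, calling of contiguous
    flexible segments (e.g. candidate long disordered regions), and
    per-residue agreement statistics against reference annotations.
    Also parses AAindex1 flat files, ranks residues within each
    propensity scale, and aggregates rank positions over scale
    collections into 20x20 rank-occupancy matrices. Includes readers
    for FASTA and PDB (sequence extraction only), a deterministic
    synthetic-sequence generator with controlled class composition,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
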