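Package: metophos
Title: Crosstalk Between Methionine Sulfoxidation and Phosphorylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical analysis of co-occurrence between protein-bound
    methionine sulfoxidation (MetO) and O-phosphorylation. Provides readers
    and validators for proteome FASTA and PTM site tables, empirical
    resampling nulls for PTM co-occurrence (plain and abundance-matched),
    sequence and spatial proximity statistics between methionines and
    phosphosites, methionine window statistics around phospho-acceptors with
    acceptor-resampling nulls, a decision-tree classifier of phosphoserine
    kinase motifs (Pro-directed, acidophilic, basophilic), hypergeometric
    term enrichment, and a synthetic proteome generator with planted effects
    for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    rlang,
    jsonlite,
    yaml,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
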