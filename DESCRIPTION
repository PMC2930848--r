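Package: promenrich
Title: Overrepresented Transcription Factor Binding Sites in Promoters of
    Co-Expressed Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies transcription factor binding sites (TFBSs) that are
    overrepresented in the promoters of a co-expressed gene set. Promoter
    windows around (optionally CAGE-refined) transcription start sites are
    scanned with JASPAR-format position weight matrices at per-matrix score
    thresholds calibrated against precomputed background hit-frequency
    tables, filtered by evolutionary conservation and coding overlap, and
    scored with fold changes, z-score p-values and proportion p-values.
    Includes Gardiner-Garden CpG island detection, alternative-TSS selection
    modes, a deterministic synthetic-fixture generator and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    optparse,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
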