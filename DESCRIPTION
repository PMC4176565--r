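Package: orichrom
Title: Nucleosome Architecture of Yeast Replication Origins from MNase-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds normalized nucleosome-positioning profiles from stranded
    mononucleosome read 5'-ends, calls nucleosome-depleted regions (NDRs) by a
    fixed coverage rule, extracts ACS-anchored and T-rich-strand-oriented
    origin windows, classifies origin chromatin architectures by k-means,
    relates classes to replication timing and intergenic context, scans
    Forkhead (RTAAAYA) consensus motifs and their dual-site spacing near the
    ACS, and measures S-vs-G1 replication dynamics with naked-DNA copy-number
    correction. Ships a synthetic-data generator with planted ground truth
    (G1 and hydroxyurea-arrested S samples plus naked controls) so every stage
    is testable end to end without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
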