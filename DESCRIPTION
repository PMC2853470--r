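Package: fragrank
Title: In Silico Fragmentation and Candidate Ranking for Tandem MS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies small molecules from tandem mass spectra by
    combinatorial bond disconnection. Candidate structures retrieved from a
    local compound library by exact mass are fragmented in silico (breadth
    first, with ring-aware double cleavage, redundancy elimination and
    neutral-loss rearrangement rules), fragments are matched to measured
    peaks under combined ppm/absolute tolerances, and candidates are ranked
    by a weighted peak count penalised by bond dissociation energies. Tied
    ranks are collapsed by Tanimoto fingerprint clustering. Includes peak
    list readers, composite-spectrum merging across collision energies,
    synthetic spectrum and decoy-library generators, and evaluation
    statistics (worst-case rank, cluster rank, positive predictive value).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
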