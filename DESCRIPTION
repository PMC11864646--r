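Package: cmatools
Title: Chaperone-Mediated Autophagy Scoring, KFERQ Motif Scanning and
    Label-Free Proteome Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing chaperone-mediated autophagy (CMA) from
    molecular data in fish and other emerging models. Implements a weighted,
    signed CMA activation score over a configurable CMA gene network with
    paralog-aware weighting (the rate-limiting LAMP2A family carries weight
    2 split across paralogs, every other family 1/n), scanning and
    classification of KFERQ-like pentapeptide targeting motifs (canonical,
    phosphorylation-generated and acetylation-generated) in protein FASTA
    files, label-free protein quantification across runs by pairwise
    median-ratio fitting with log-space least-squares reconstruction and
    fold-change/p-value differential calling, qPCR relative-expression
    arithmetic (efficiency-corrected E-method and delta-Ct), motif-class
    enrichment between protein sets, and seeded synthetic-data generators
    with ground truth for every pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
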