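Package: fearmiR
Title: Seed-Match Target Networks and Induction Classes for Learning-Induced Hippocampal miRNAs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Reusable in-silico pipeline around learning-induced hippocampal
    microRNAs: canonical seed-match site scanning of 3'UTRs (8mer, 7mer-m8,
    7mer-A1, 6mer) with a seed-mutation operator, brain-expression filtering
    and multi-miRNA co-targeting of predicted targets, permutation-based
    pathway over-representation against random brain-expressed gene sets with
    a hypergeometric oracle, miRNA ranking by pathway target counts,
    reference-normalized fold-change computation with replicate-wise
    induction filtering and Class I/II/III assignment, inter-replicate
    concordance versus random feature panels, and closed-form normalizations
    for FM4-64 destaining, FRAP recovery and dual-luciferase knockdown.
    Includes seeded synthetic-data generators with planted ground truth for
    every structure the pipeline is meant to recover.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
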