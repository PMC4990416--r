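Package: refsel
Title: Reference Gene Selection and Efficiency-Corrected Quantification for qPCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete workflow for selecting stable reference (housekeeping)
    genes from candidate panels in quantitative PCR experiments and using them
    to normalise and compare transcript levels. Fits standard curves in log2
    space and converts quantification cycles (Ct) to efficiency-corrected log2
    relative quantities; ranks candidate genes with the geNorm stability
    measure M and pairwise-variation criterion, and with the NormFinder
    inter/intra-group variance model, including a nested-loop all-combinations
    selection procedure; tests selection robustness by leave-one-group-out
    perturbation; builds multi-gene normalisation factors; compares groups
    with a gene-specific-variance model and Bonferroni-corrected contrasts;
    verifies primer/probe exon-junction layout in silico; and simulates
    complete qPCR experiments with a truth ledger for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme,
    optparse,
    yaml
Config/testthat/edition: 3
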