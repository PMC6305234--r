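Package: demotif
Title: Context Analysis of Diacidic DE Motifs in Unconventional Protein
    Secretion
Version: 1.0.0
Authors@R:
    person("Motif", "Context Lab", email = "maintainer@demotif.dev",
           role = c("aut", "cre"))
Description: Scans protein sequences for diacidic (DE) motifs and related
    short linear motifs (phosphorylatable diacidic insertions, LC3
    interacting regions), computes windowed physicochemical context
    features (flanking hydrophobicity, flanking charge, and a three-state
    structural order class), enumerates the sixteen "most relevant DE"
    selection hypotheses, fits binary logistic regression models by
    iteratively reweighted least squares with Wald and likelihood-ratio
    inference, performs 2x2 contingency analysis with Fisher's exact test
    and odds ratios, and runs a simplified statistical-coupling-analysis
    style co-evolution pipeline on consensus-binarized multiple sequence
    alignments. A seeded synthetic-data generator with known ground truth
    makes every pipeline stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
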