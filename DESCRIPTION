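Package: rifchase
Title: Rifampicin-Chase Transcript Stability, Differential Expression and
    Fluctuation-Test Analysis for Bacterial RNA Decay Studies
Version: 0.1.0
Authors@R:
    person("Francesca", "Rivera", email = "f.rivera@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing bacterial transcriptome stability measured
    by rifampicin chase RNA-Seq (percent-remaining classification into four
    stability categories and between-strain comparisons), threshold-based
    differential expression on count matrices (CPM, TMM normalization, a
    negative-binomial two-group exact-style test, Benjamini-Hochberg FDR),
    mutation-rate estimation from Luria-Delbrueck fluctuation assays via the
    Lea-Coulson median estimator, and phenotype quantifications (generation
    time, protein half-life, ROS normalization, relative densitometry,
    molecules-per-cell arithmetic, ANOVA with Tukey letters). A seeded
    synthetic-data generator emulates the assumed data structure so that
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    jsonlite,
    optparse
Config/testthat/edition: 3
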