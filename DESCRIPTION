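Package: txrecovery
Title: Transcriptomic Recovery Scoring for Antisense Oligonucleotide Treatments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates how far a treatment returns a diseased transcriptome
    toward its healthy state in a control / disease / treated RNA-seq design.
    Implements negative-binomial differential expression with median-of-ratios
    normalization and a conditional exact test, per-gene percent-recovery
    scoring with categorical binning, reversal and intersection-ratio
    summaries, hard-target (miRNA target list) specificity reports, and
    percent-spliced-in (PSI/dPSI) splicing-event recovery with Fisher exact
    testing. Includes a ground-truth synthetic data generator for the
    four-group design (control, disease, and blockmiR-like / antagomiR-like
    treatment arms) plus assay-level formulas: viability normalization and
    four-parameter logistic TC50 fits, 2^-ddCt relative expression, mean pixel
    intensity, grip-strength normalization, and central-nuclei percentages.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
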