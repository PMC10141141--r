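#!/usr/bin/env Rscript
# Stage 2: differential expression.
#
# Calls altered genes (BH-adjusted p < 0.05 and |log2FC| >= 1) for the
# control-vs-disease contrast and for disease vs each treatment arm, using
# median-of-ratios normalization and the conditional exact NB test.

library(txrecovery)

data_dir <- "results/data"
out <- "results/dge"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cm <- read_count_matrix(file.path(data_dir, "counts.tsv"),
                        file.path(data_dir, "design.tsv"))
arms <- setdiff(unique(cm$design$group), c("CNT", "DIS"))

dge_dis <- test_differential(cm, "CNT", "DIS")
write_dge_table(dge_dis, file.path(out, "dge_CNT_vs_DIS.tsv"))
message(sprintf("CNT vs DIS: %d/%d genes altered (disease-related)",
                length(call_altered(dge_dis)), nrow(dge_dis)))

for (arm in arms) {
  d <- test_differential(cm, "DIS", arm)
  write_dge_table(d, file.path(out, sprintf("dge_DIS_vs_%s.tsv", arm)))
  message(sprintf("DIS vs %-9s: %d genes altered", arm,
                  length(call_altered(d))))
}
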