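#!/usr/bin/env Rscript
# Stage 3: percent recovery, reversals, intersection ratios, hard targets.
#
# Scores every gene's return toward control expression under each arm, bins
# the disease-related genes into the recovery categories, calls reversals
# (treatment-altered disease genes moving against their disease direction),
# and reports the hard-target specificity contrast between the arms.

library(txrecovery)

data_dir <- "results/data"; dge_dir <- "results/dge"
out <- "results/recovery"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cm <- read_count_matrix(file.path(data_dir, "counts.tsv"),
                        file.path(data_dir, "design.tsv"))
arms <- setdiff(unique(cm$design$group), c("CNT", "DIS"))
dge_dis <- read_dge_table(file.path(dge_dir, "dge_CNT_vs_DIS.tsv"))
disease_set <- disease_related_genes(dge_dis)

tables <- list(); dges <- list()
for (arm in arms) {
  d <- read_dge_table(file.path(dge_dir, sprintf("dge_DIS_vs_%s.tsv", arm)))
  dges[[arm]] <- d
  rv <- reversal_calls(disease_set, d)
  message(sprintf(
    "%-9s: %d treatment-altered genes, %d reversals (%.1f%%)",
    arm, rv$n_treatment_altered, length(rv$reversals),
    100 * rv$reversal_fraction))
  tables[[arm]] <- build_recovery_table(cm, "CNT", "DIS", arm,
                                        disease_set = disease_set,
                                        reversals = rv$reversals)
  write.table(as.data.frame(tables[[arm]]),
              file.path(out, sprintf("recovery_%s.tsv", arm)),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

s <- recovery_summary(tables)
message("recovery categories over disease-related genes:")
print(s$category_counts)
message(sprintf("recovered-set intersection ratio(s): %s",
                paste(sprintf("%s=%.3f", names(s$intersection_ratios),
                              s$intersection_ratios), collapse = ", ")))
write.table(data.frame(arm = rownames(s$category_counts),
                       s$category_counts),
            file.path(out, "category_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

targets <- readLines(file.path(data_dir, "hard_targets.txt"))
ht <- hard_target_report(dges, targets)
message(sprintf("altered hard targets of %d: %s", length(targets),
                paste(sprintf("%s=%d", names(ht$altered_counts),
                              ht$altered_counts), collapse = ", ")))
write.table(data.frame(gene = rownames(ht$log2fc), ht$log2fc,
                       check.names = FALSE),
            file.path(out, "hard_targets_log2fc.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
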