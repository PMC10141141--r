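#!/usr/bin/env Rscript
# Stage 1: simulate the study-like dataset.
#
# Four groups (control CNT, disease DIS, a site-directed blockmiR-like arm
# and a miRNA-directed antagomiR-like arm), 4 replicates each, 2000 genes of
# which 10% carry a disease effect of 1-2.5 log2 units. Both arms restore
# 80% of the disease shift; only the antagomiR-like arm additionally
# perturbs off-target genes. A 57-gene hard-target list is drawn from the
# non-disease genes. Splicing: 200 events, 30 shifted by -40 PSI in disease,
# treatment restores them in proportion to each arm's recovery fraction.

library(txrecovery)

seed <- 20230415L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(
  n_genes = 2000, n_samples_per_group = 4, seed = seed,
  frac_disease_genes = 0.1, effect_log2_range = c(1, 2.5),
  dispersion = 0.1, off_target_log2_magnitude = 2,
  treatments = list(
    blockmir  = list(recovery_fraction = 0.8, off_target_rate = 0,
                     antagomir_like = FALSE),
    antagomir = list(recovery_fraction = 0.8, off_target_rate = 0.3,
                     antagomir_like = TRUE)))
sim <- simulate_counts(cfg)

write_count_matrix(sim$counts,
                   file.path(out, "counts.tsv"),
                   file.path(out, "design.tsv"))

truth <- data.frame(
  gene = sim$truth$gene_ids,
  is_disease_gene = sim$truth$is_disease_gene,
  delta_log2 = sim$truth$delta_log2,
  off_target_antagomir = sim$truth$arms$antagomir$is_off_target)
write.table(truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

targets <- sim$truth$gene_ids[!sim$truth$is_disease_gene][1:57]
writeLines(targets, file.path(out, "hard_targets.txt"))

psi_ctl <- rep(60, 200)
psi_dis <- psi_ctl; psi_dis[1:30] <- 20
true_psi <- cbind(CNT = psi_ctl, DIS = psi_dis,
                  blockmir  = psi_dis + 0.8 * (psi_ctl - psi_dis),
                  antagomir = psi_dis + 0.8 * (psi_ctl - psi_dis))
ev <- simulate_splice_events(true_psi, n_samples_per_group = 4,
                             coverage_mean = 100, seed = seed + 1L)
write.table(ev$events, file.path(out, "splice_events.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("wrote %d genes x %d samples, %d disease genes, %d targets",
                nrow(sim$counts$counts), ncol(sim$counts$counts),
                sum(truth$is_disease_gene), length(targets)))
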