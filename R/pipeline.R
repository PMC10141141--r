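#' Pipeline run configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]: either a
#' simulation recipe or paths to a counts/design TSV pair, the contrast
#' layout, every analysis threshold, and the output directory. All study
#' thresholds live here, never hard-coded downstream.
#'
#' @param sim a [sim_config()] (mutually exclusive with `counts_path`).
#' @param counts_path,design_path input TSVs as written by
#'   [write_count_matrix()] (used when `sim` is `NULL`).
#' @param control,disease group labels of the control and disease groups.
#' @param treatments treatment-arm group labels; default: every other group.
#' @param hard_targets optional character vector of hard-target gene ids, or
#'   a path to a one-symbol-per-line text file.
#' @param splicing optional list configuring the splicing stage:
#'   `n_events`, `n_shifted`, `dpsi_shift`, `coverage_mean`,
#'   `n_samples_per_group` (simulated alongside the counts), or
#'   `events_path` to read a long-format event TSV instead.
#' @param alpha,lfc DGE thresholds.
#' @param bins recovery category boundaries.
#' @param eps percent-recovery denominator guard (normalized counts).
#' @param min_dpsi,min_reads,splice_alpha,min_move splicing thresholds.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed governing every random draw.
#' @param quiet suppress progress messages.
#' @return validated `run_config` list.
#' @export
run_config <- function(sim = NULL, counts_path = NULL, design_path = NULL,
                       control = "CNT", disease = "DIS", treatments = NULL,
                       hard_targets = NULL, splicing = list(),
                       alpha = 0.05, lfc = 1, bins = c(10, 50, 150),
                       eps = 1, min_dpsi = 25, min_reads = 10,
                       splice_alpha = 0.05, min_move = 5,
                       out_dir = "results/run", seed = 1L, quiet = FALSE) {
  if (is.null(sim) && is.null(counts_path))
    stop("provide either a sim_config or counts/design paths")
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  stopifnot(alpha > 0, lfc > 0, min_dpsi >= 0, min_reads >= 0,
            splice_alpha > 0, min_move >= 0, eps >= 0)
  if (is.character(hard_targets) && length(hard_targets) == 1 &&
      file.exists(hard_targets))
    hard_targets <- readLines(hard_targets)
  structure(list(sim = sim, counts_path = counts_path,
                 design_path = design_path,
                 control = control, disease = disease,
                 treatments = treatments, hard_targets = hard_targets,
                 splicing = splicing,
                 alpha = alpha, lfc = lfc, bins = bins, eps = eps,
                 min_dpsi = min_dpsi, min_reads = min_reads,
                 splice_alpha = splice_alpha, min_move = min_move,
                 out_dir = out_dir, seed = as.integer(seed),
                 quiet = isTRUE(quiet)),
            class = "run_config")
}

pipe_msg <- function(config, ...) {
  if (!config$quiet) message(sprintf(...))
}

#' Run the full recovery pipeline
#'
#' Executes, in order: data acquisition (simulation or TSV input), DGE for
#' the control-vs-disease contrast, disease-gene calling, per-arm
#' disease-vs-treated DGE with reversal calls and recovery tables, the
#' cross-arm recovery summary with intersection ratios, the hard-target
#' specificity report (when a target list is given), and the splicing-event
#' analysis per arm. Every intermediate table is written under
#' `config$out_dir` and a manifest records the seed, thresholds, and an md5
#' checksum of every file, so two runs with one seed produce byte-identical
#' bundles.
#'
#' @param config a [run_config()].
#' @return invisibly, a `run_report` list with all in-memory stage outputs
#'   and the summary written to disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  # --- stage: data ---------------------------------------------------------
  if (!is.null(config$sim)) {
    pipe_msg(config, "simulating counts (seed %d)", config$seed)
    sim <- simulate_counts(config$sim)
    cm <- sim$counts
    truth <- sim$truth
  } else {
    pipe_msg(config, "reading counts from %s", config$counts_path)
    cm <- read_count_matrix(config$counts_path, config$design_path)
    truth <- NULL
  }
  groups <- unique(cm$design$group)
  for (g in c(config$control, config$disease))
    if (!g %in% groups)
      stop(sprintf("contrast group '%s' missing from the design", g))
  arms <- config$treatments %||%
    setdiff(groups, c(config$control, config$disease))
  if (length(arms) == 0) stop("no treatment arms in the design")
  bad <- setdiff(arms, groups)
  if (length(bad) > 0)
    stop(sprintf("treatment group(s) missing from the design: %s",
                 paste(bad, collapse = ", ")))
  write_count_matrix(cm, file.path(config$out_dir, "counts.tsv"),
                     file.path(config$out_dir, "design.tsv"))

  # --- stage: dge ----------------------------------------------------------
  pipe_msg(config, "DGE: %s vs %s", config$control, config$disease)
  dge_dis <- test_differential(cm, config$control, config$disease,
                               alpha = config$alpha, lfc = config$lfc)
  write_dge_table(dge_dis, file.path(config$out_dir, "dge_disease.tsv"))
  disease_set <- disease_related_genes(dge_dis, alpha = config$alpha,
                                       lfc = config$lfc)

  dge_arms <- list(); reversals <- list(); rec_tables <- list()
  for (arm in arms) {
    pipe_msg(config, "DGE: %s vs %s", config$disease, arm)
    d <- test_differential(cm, config$disease, arm,
                           alpha = config$alpha, lfc = config$lfc)
    dge_arms[[arm]] <- d
    write_dge_table(d, file.path(config$out_dir,
                                 sprintf("dge_%s.tsv", arm)))
    reversals[[arm]] <- reversal_calls(disease_set, d,
                                       alpha = config$alpha,
                                       lfc = config$lfc)
    rec_tables[[arm]] <- build_recovery_table(
      cm, config$control, config$disease, arm,
      disease_set = disease_set, reversals = reversals[[arm]]$reversals,
      eps = config$eps, bins = config$bins)
    utils::write.table(as.data.frame(rec_tables[[arm]]),
                       file.path(config$out_dir,
                                 sprintf("recovery_%s.tsv", arm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  rec_summary <- recovery_summary(rec_tables)

  # --- stage: hard targets -------------------------------------------------
  targets_report <- NULL
  if (!is.null(config$hard_targets)) {
    pipe_msg(config, "hard-target report (%d targets)",
             length(config$hard_targets))
    targets_report <- hard_target_report(dge_arms, config$hard_targets)
    utils::write.table(
      data.frame(gene = rownames(targets_report$log2fc),
                 targets_report$log2fc, check.names = FALSE),
      file.path(config$out_dir, "hard_targets_log2fc.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- stage: splicing -----------------------------------------------------
  splice_tables <- list(); splice_summaries <- list()
  sp <- config$splicing
  if (!is.null(sp$events_path)) {
    events <- utils::read.delim(sp$events_path, stringsAsFactors = FALSE)
  } else {
    n_events <- sp$n_events %||% 200
    n_shifted <- sp$n_shifted %||% 30
    dpsi_shift <- sp$dpsi_shift %||% -40
    coverage_mean <- sp$coverage_mean %||% 100
    nspg <- sp$n_samples_per_group %||%
      (if (!is.null(config$sim)) config$sim$n_samples_per_group else 4)
    pipe_msg(config, "simulating %d splice events", n_events)
    psi_ctl <- rep(60, n_events)
    psi_dis <- psi_ctl
    psi_dis[seq_len(n_shifted)] <- pmin(100, pmax(0,
      psi_ctl[seq_len(n_shifted)] + dpsi_shift))
    true_psi <- cbind(psi_ctl, psi_dis)
    colnames(true_psi) <- c(config$control, config$disease)
    for (arm in arms) {
      rho <- if (!is.null(config$sim))
        config$sim$treatments[[arm]]$recovery_fraction %||% 1 else 1
      psi_tr <- psi_dis + rho * (psi_ctl - psi_dis)
      true_psi <- cbind(true_psi, pmin(100, pmax(0, psi_tr)))
      colnames(true_psi)[ncol(true_psi)] <- arm
    }
    events <- simulate_splice_events(true_psi, n_samples_per_group = nspg,
                                     coverage_mean = coverage_mean,
                                     seed = config$seed + 1000L)$events
  }
  utils::write.table(events, file.path(config$out_dir, "splice_events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (arm in arms) {
    st <- analyze_splicing(events, config$control, config$disease, arm,
                           min_dpsi = config$min_dpsi,
                           min_reads = config$min_reads,
                           alpha = config$splice_alpha,
                           min_move = config$min_move)
    splice_tables[[arm]] <- st
    splice_summaries[[arm]] <- splicing_summary(st)
    utils::write.table(as.data.frame(st),
                       file.path(config$out_dir,
                                 sprintf("splicing_%s.tsv", arm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  report <- list(counts = cm, truth = truth,
                 dge_disease = dge_dis, disease_set = disease_set,
                 dge_arms = dge_arms, reversals = reversals,
                 recovery_tables = rec_tables,
                 recovery_summary = rec_summary,
                 hard_targets = targets_report,
                 splice_tables = splice_tables,
                 splice_summaries = splice_summaries,
                 config = config)
  class(report) <- "run_report"
  write_report(report, config$out_dir)
  invisible(report)
}

#' Write the machine-readable run summary and manifest
#'
#' Serializes the headline numbers of a pipeline run — disease-gene count,
#' per-arm altered counts, reversal fractions, recovery category counts,
#' intersection ratios, hard-target altered counts, and filtered/reversed
#' splice-event counts — to `summary.json`, then writes `manifest.json`
#' recording the schema version, seed, thresholds, and an md5 checksum for
#' every file in the bundle. No timestamps are recorded, so identical runs
#' produce identical bundles.
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param out_dir directory holding the bundle.
#' @return invisibly, the summary list.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "run_report"))
  cfg <- report$config
  arms <- names(report$dge_arms)
  summary <- list(
    schema = "txrecovery/run-summary/1",
    n_genes = nrow(report$counts$counts),
    n_disease_related = nrow(report$disease_set),
    arms = lapply(stats::setNames(arms, arms), function(a) {
      rv <- report$reversals[[a]]
      ss <- report$splice_summaries[[a]]
      list(
        n_treatment_altered = rv$n_treatment_altered,
        n_reversals = length(rv$reversals),
        reversal_fraction = rv$reversal_fraction,
        category_counts =
          as.list(report$recovery_summary$category_counts[a, ]),
        n_altered_hard_targets = if (!is.null(report$hard_targets))
          unname(report$hard_targets$altered_counts[a]) else NULL,
        splicing = ss)
    }),
    intersection_ratios =
      as.list(report$recovery_summary$intersection_ratios),
    thresholds = list(alpha = cfg$alpha, lfc = cfg$lfc, bins = cfg$bins,
                      eps = cfg$eps, min_dpsi = cfg$min_dpsi,
                      min_reads = cfg$min_reads,
                      splice_alpha = cfg$splice_alpha,
                      min_move = cfg$min_move),
    seed = cfg$seed)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(schema = "txrecovery/manifest/1",
                   seed = cfg$seed,
                   thresholds = summary$thresholds,
                   files = as.list(stats::setNames(unname(sums), files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(summary)
}
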