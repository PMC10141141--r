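#' Per-gene percent recovery
#'
#' The rescue statistic: the fraction of the disease-induced shift in mean
#' expression that treatment undoes,
#' `100 * (treated - disease) / (control - disease)`, computed on mean
#' normalized counts. 0 means the treated group sits at the disease mean,
#' 100 means it returned to the control mean, values above 100 overshoot.
#' When control and disease means are closer than `eps` normalized counts the
#' ratio is unstable and the result is marked undefined (`NA`), never an
#' error.
#'
#' @param mean_control,mean_disease,mean_treated non-negative mean normalized
#'   counts (vectorized).
#' @param eps denominator guard, in normalized counts.
#' @return numeric percent recovery; `NA` where the guard trips.
#' @export
percent_recovery <- function(mean_control, mean_disease, mean_treated,
                             eps = 1) {
  if (any(c(mean_control, mean_disease, mean_treated) < 0, na.rm = TRUE))
    stop("mean counts must be non-negative")
  denom <- mean_control - mean_disease
  out <- 100 * (mean_treated - mean_disease) / denom
  out[abs(denom) < eps] <- NA_real_
  out
}

#' Recovery categories
#'
#' Bins percent-recovery values: unrecovered below 10 (including negative
#' values, where treatment moved expression further from control), partial in
#' \[10, 50), total in \[50, 150\], over-recovered above 150. Undefined (`NA`)
#' values pass through as `"undefined"`.
#'
#' @param pct percent recovery (vectorized; `NA` allowed).
#' @param bins boundaries `c(partial, total, over)`; defaults `c(10, 50, 150)`.
#' @return character vector of categories.
#' @export
classify_recovery <- function(pct, bins = c(10, 50, 150)) {
  stopifnot(length(bins) == 3, !is.unsorted(bins))
  out <- rep("undefined", length(pct))
  ok <- !is.na(pct)
  out[ok & pct < bins[1]] <- "unrecovered"
  out[ok & pct >= bins[1] & pct < bins[2]] <- "partial"
  out[ok & pct >= bins[2] & pct <= bins[3]] <- "total"
  out[ok & pct > bins[3]] <- "over"
  out
}

#' Disease-related genes from the control-vs-disease contrast
#'
#' The altered genes of the control-vs-disease comparison, each with the
#' direction of its disease change recorded (direction of disease relative to
#' control).
#'
#' @param dge a `dge_result` for the control (reference) vs disease
#'   (comparison) contrast.
#' @param alpha,lfc thresholds passed to [call_altered()].
#' @return data.frame with columns `gene` and `direction` ("up"/"down" in
#'   disease).
#' @export
disease_related_genes <- function(dge, alpha = 0.05, lfc = 1) {
  genes <- call_altered(dge, alpha = alpha, lfc = lfc)
  sub <- dge[match(genes, dge$gene), c("gene", "log2fc")]
  data.frame(gene = sub$gene,
             direction = ifelse(sub$log2fc > 0, "up", "down"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Treatment-induced reversals of the disease signature
#'
#' A reversal is a disease-related gene that the treated-vs-disease contrast
#' calls altered in the direction opposing its disease change (a gene up in
#' disease must come down under treatment, and vice versa). Also reports the
#' fraction of all treatment-altered genes that are reversals — the summary
#' statistic quoted for each arm — and any disease genes absent from the
#' treatment contrast.
#'
#' @param disease_set data.frame from [disease_related_genes()].
#' @param dge_treat a `dge_result` for the disease (reference) vs treated
#'   (comparison) contrast.
#' @param alpha,lfc thresholds for the treatment alteration call.
#' @return list with `reversals` (gene ids), `n_treatment_altered`,
#'   `reversal_fraction` (reversals / treatment-altered genes),
#'   `improvement_fraction` (treatment-altered disease genes moving opposite
#'   their disease direction, regardless of the joint altered call, over
#'   treatment-altered genes), and `missing_genes`.
#' @export
reversal_calls <- function(disease_set, dge_treat, alpha = 0.05, lfc = 1) {
  stopifnot(is.data.frame(disease_set),
            all(c("gene", "direction") %in% names(disease_set)))
  altered <- call_altered(dge_treat, alpha = alpha, lfc = lfc)
  missing <- setdiff(disease_set$gene, dge_treat$gene)

  idx <- match(disease_set$gene, dge_treat$gene)
  treat_lfc <- dge_treat$log2fc[idx]
  opposes <- (disease_set$direction == "up" & treat_lfc < 0) |
    (disease_set$direction == "down" & treat_lfc > 0)
  is_altered <- disease_set$gene %in% altered
  rev_genes <- disease_set$gene[!is.na(opposes) & opposes & is_altered]

  n_alt <- length(altered)
  list(
    reversals = rev_genes,
    n_treatment_altered = n_alt,
    reversal_fraction = if (n_alt > 0) length(rev_genes) / n_alt else NA_real_,
    improvement_fraction = if (n_alt > 0)
      sum(!is.na(opposes) & opposes & is_altered) / n_alt else NA_real_,
    missing_genes = missing
  )
}

#' Intersection ratio of two gene sets
#'
#' `|A intersect B| / |A union B|` (the Jaccard index), used to quantify how
#' much two treatment arms act on the same genes. Two empty sets give 0 with
#' a warning.
#'
#' @param set_a,set_b character vectors.
#' @return ratio in \[0, 1\].
#' @export
intersection_ratio <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  u <- length(union(a, b))
  if (u == 0) {
    warning("both sets empty; intersection ratio defined as 0")
    return(0)
  }
  length(intersect(a, b)) / u
}

#' Build the per-gene recovery table for one treatment arm
#'
#' Computes mean normalized counts for the control, disease and treated
#' groups, percent recovery and its category for every gene, and flags
#' disease-related genes and reversals.
#'
#' @param x a [count_matrix()].
#' @param control,disease,treated group labels.
#' @param disease_set data.frame from [disease_related_genes()] (may be
#'   `NULL`: no genes flagged).
#' @param reversals character vector of reversal gene ids (may be `NULL`).
#' @param eps denominator guard for [percent_recovery()].
#' @param bins category boundaries for [classify_recovery()].
#' @return a `recovery_table` data.frame: gene, mean_control, mean_disease,
#'   mean_treated, pct_recovery, category, is_disease_gene, reversal.
#' @export
build_recovery_table <- function(x, control, disease, treated,
                                 disease_set = NULL, reversals = NULL,
                                 eps = 1, bins = c(10, 50, 150)) {
  stopifnot(inherits(x, "count_matrix"))
  norm <- normalize_counts(x)$normalized
  mc <- rowMeans(norm[, group_samples(x, control), drop = FALSE])
  md <- rowMeans(norm[, group_samples(x, disease), drop = FALSE])
  mt <- rowMeans(norm[, group_samples(x, treated), drop = FALSE])
  pct <- percent_recovery(mc, md, mt, eps = eps)
  res <- data.frame(
    gene = rownames(norm),
    mean_control = mc, mean_disease = md, mean_treated = mt,
    pct_recovery = pct,
    category = classify_recovery(pct, bins = bins),
    is_disease_gene = rownames(norm) %in% (disease_set$gene %||% character(0)),
    reversal = rownames(norm) %in% (reversals %||% character(0)),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "groups") <- c(control = control, disease = disease,
                           treated = treated)
  class(res) <- c("recovery_table", "data.frame")
  res
}

#' Cross-arm recovery summary
#'
#' Category counts over disease-related genes for each treatment arm, plus
#' the shared / exclusive breakdown of recovered genes (category partial,
#' total or over) between arms with pairwise intersection ratios.
#'
#' @param tables named list of `recovery_table`s, one per treatment arm, all
#'   over the same gene universe.
#' @return list with `category_counts` (arm x category matrix),
#'   `recovered_sets` (per arm), `shared` and `exclusive` gene sets and
#'   `intersection_ratios` for each arm pair.
#' @export
recovery_summary <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1, !is.null(names(tables)))
  universe <- tables[[1]]$gene
  for (tb in tables)
    if (!identical(sort(tb$gene), sort(universe)))
      stop("recovery tables must share one gene universe")

  cats <- c("unrecovered", "partial", "total", "over", "undefined")
  counts <- t(vapply(tables, function(tb) {
    d <- tb[tb$is_disease_gene, ]
    vapply(cats, function(cc) sum(d$category == cc), integer(1))
  }, integer(length(cats))))
  colnames(counts) <- cats

  recovered <- lapply(tables, function(tb)
    tb$gene[tb$is_disease_gene &
              tb$category %in% c("partial", "total", "over")])

  pairs <- if (length(tables) >= 2)
    utils::combn(names(tables), 2, simplify = FALSE) else list()
  ir <- vapply(pairs, function(p)
    intersection_ratio(recovered[[p[1]]], recovered[[p[2]]]), numeric(1))
  names(ir) <- vapply(pairs, paste, character(1), collapse = "_vs_")

  shared <- if (length(recovered) > 1) Reduce(intersect, recovered)
            else recovered[[1]]
  exclusive <- lapply(names(recovered), function(nm)
    setdiff(recovered[[nm]], unlist(recovered[setdiff(names(recovered), nm)])))
  names(exclusive) <- names(recovered)

  list(category_counts = counts, recovered_sets = recovered,
       shared = shared, exclusive = exclusive, intersection_ratios = ir)
}

#' Hard-target specificity report
#'
#' For a list of experimentally supported miRNA target genes ("hard
#' targets"), tabulates each target's log2 fold change and altered flag in
#' every supplied contrast and counts altered targets per contrast — the
#' specificity readout distinguishing a binding-site-directed treatment (few
#' altered targets) from a miRNA-directed one (many).
#'
#' @param dge_list named list of `dge_result`s, one per contrast.
#' @param targets character vector of target gene ids.
#' @return list with `log2fc` and `altered` (target x contrast matrices),
#'   `altered_counts` per contrast, and `missing_targets` absent from every
#'   contrast's tested genes.
#' @export
hard_target_report <- function(dge_list, targets) {
  stopifnot(is.list(dge_list), length(dge_list) >= 1,
            !is.null(names(dge_list)))
  targets <- unique(as.character(targets))
  if (length(targets) == 0) stop("empty target list")
  tested <- unique(unlist(lapply(dge_list, `[[`, "gene")))
  present <- intersect(targets, tested)
  if (length(present) == 0)
    stop("no hard target present in the tested genes")
  missing <- setdiff(targets, tested)

  lfc <- sapply(dge_list, function(d) d$log2fc[match(present, d$gene)])
  alt <- sapply(dge_list, function(d) {
    a <- d$altered[match(present, d$gene)]
    !is.na(a) & a
  })
  lfc <- matrix(lfc, nrow = length(present),
                dimnames = list(present, names(dge_list)))
  alt <- matrix(alt, nrow = length(present),
                dimnames = list(present, names(dge_list)))
  list(log2fc = lfc, altered = alt,
       altered_counts = colSums(alt),
       missing_targets = missing)
}
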