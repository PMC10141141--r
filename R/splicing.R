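#' Percent spliced-in
#'
#' PSI = 100 * inclusion / (inclusion + exclusion). Undefined (`NA`) when an
#' event has no informative reads.
#'
#' @param inclusion,exclusion non-negative read counts (vectorized).
#' @return PSI in \[0, 100\], `NA` at zero coverage.
#' @export
compute_psi <- function(inclusion, exclusion) {
  if (any(inclusion < 0, na.rm = TRUE) || any(exclusion < 0, na.rm = TRUE))
    stop("read counts must be non-negative")
  tot <- inclusion + exclusion
  out <- 100 * inclusion / tot
  out[tot == 0] <- NA_real_
  out
}

#' Exact test for one splicing event between two groups
#'
#' Two-sided Fisher exact test on the pooled 2x2 inclusion/exclusion table.
#'
#' @param inc_a,exc_a pooled inclusion/exclusion reads in group A.
#' @param inc_b,exc_b pooled reads in group B.
#' @return p-value in \[0, 1\].
#' @export
test_event <- function(inc_a, exc_a, inc_b, exc_b) {
  counts <- c(inc_a, exc_a, inc_b, exc_b)
  if (any(counts < 0)) stop("read counts must be non-negative")
  if (sum(counts) == 0) return(1)
  stats::fisher.test(matrix(round(counts), nrow = 2))$p.value
}

#' Event filter at the study thresholds
#'
#' Retains events with |dPSI| strictly greater than `min_dpsi` percentage
#' points, at least `min_reads` pooled informative reads in each of the two
#' groups, and BH-adjusted p below `alpha`. Events with undefined dPSI never
#' pass.
#'
#' @param table data.frame holding at least `dpsi`, `padj`, `reads_a`,
#'   `reads_b` columns (as built by [analyze_splicing()]).
#' @param min_dpsi minimum absolute dPSI (percentage points, exclusive).
#' @param min_reads minimum pooled reads per group (inclusive).
#' @param alpha adjusted-p threshold.
#' @return logical vector, one flag per event.
#' @export
filter_events <- function(table, min_dpsi = 25, min_reads = 10,
                          alpha = 0.05) {
  stopifnot(all(c("dpsi", "padj", "reads_a", "reads_b") %in% names(table)))
  ok <- !is.na(table$dpsi) & abs(table$dpsi) > min_dpsi &
    table$reads_a >= min_reads & table$reads_b >= min_reads &
    !is.na(table$padj) & table$padj < alpha
  ok
}

#' Splicing reversal call
#'
#' An event reverses when the treated-vs-disease PSI shift opposes the sign
#' of the disease-vs-control shift and moves by at least `min_move`
#' percentage points. Undefined inputs give an undefined (`NA`) flag.
#'
#' @param dpsi_disease disease-minus-control dPSI.
#' @param dpsi_treated treated-minus-disease dPSI.
#' @param min_move minimum |treated dPSI| to count (percentage points).
#' @return logical (vectorized), `NA` where either dPSI is undefined.
#' @export
event_reversal <- function(dpsi_disease, dpsi_treated, min_move = 5) {
  ifelse(is.na(dpsi_disease) | is.na(dpsi_treated), NA,
         sign(dpsi_disease) * sign(dpsi_treated) < 0 &
           abs(dpsi_treated) >= min_move)
}

#' Percent splicing recovery
#'
#' The splicing analogue of percent recovery:
#' `100 * (psi_treated - psi_disease) / (psi_control - psi_disease)`.
#' Undefined when the disease shift is smaller than `eps` percentage points.
#' Accepts pre-quantified PSI-like percentages (e.g., gel densitometry
#' ratios) as well as junction-read PSI.
#'
#' @param psi_control,psi_disease,psi_treated PSI values (vectorized).
#' @param eps denominator guard in percentage points.
#' @return PSR in percent, `NA` where undefined.
#' @export
percent_splicing_recovery <- function(psi_control, psi_disease, psi_treated,
                                      eps = 1) {
  denom <- psi_control - psi_disease
  out <- 100 * (psi_treated - psi_disease) / denom
  out[is.na(denom) | abs(denom) < eps] <- NA_real_
  out
}

#' Full splicing-event analysis for one treatment arm
#'
#' Pools junction reads per group (reads are summed across a group's samples
#' before PSI is computed), derives per-group PSI, disease-vs-control and
#' treated-vs-disease dPSI, Fisher exact p-values with BH adjustment across
#' events, the study filter, reversal flags and PSR.
#'
#' @param events long-format data.frame with columns `event_id`, `gene`,
#'   `sample`, `inclusion`, `exclusion` and either a `group` column or a
#'   `design` mapping.
#' @param control,disease,treated group labels.
#' @param design optional data.frame (`sample`, `group`) when `events` lacks
#'   a group column.
#' @param min_dpsi,min_reads,alpha filter thresholds (see [filter_events()]).
#' @param min_move reversal threshold (see [event_reversal()]).
#' @return a `splice_event_table` data.frame with one row per event:
#'   pooled reads and PSI per group, `dpsi` (disease - control), `pvalue`,
#'   `padj`, `reads_a`/`reads_b` (control/disease pooled totals),
#'   `passes_filter`, `dpsi_treated` (treated - disease), `reversed`, `psr`.
#' @export
analyze_splicing <- function(events, control, disease, treated,
                             design = NULL, min_dpsi = 25, min_reads = 10,
                             alpha = 0.05, min_move = 5) {
  req <- c("event_id", "gene", "sample", "inclusion", "exclusion")
  stopifnot(all(req %in% names(events)))
  if (!"group" %in% names(events)) {
    if (is.null(design)) stop("need a 'group' column or a design")
    events$group <- design$group[match(events$sample, design$sample)]
  }
  for (g in c(control, disease, treated))
    if (!g %in% events$group) stop(sprintf("group '%s' absent from events", g))

  pool <- function(g) {
    sub <- events[events$group == g, ]
    inc <- tapply(sub$inclusion, sub$event_id, sum)
    exc <- tapply(sub$exclusion, sub$event_id, sum)
    data.frame(event_id = names(inc), inc = as.numeric(inc),
               exc = as.numeric(exc), stringsAsFactors = FALSE)
  }
  pc <- pool(control); pd <- pool(disease); pt <- pool(treated)
  ids <- sort(unique(events$event_id))
  gene <- events$gene[match(ids, events$event_id)]
  ic <- pc$inc[match(ids, pc$event_id)]; ec <- pc$exc[match(ids, pc$event_id)]
  id_ <- pd$inc[match(ids, pd$event_id)]; ed <- pd$exc[match(ids, pd$event_id)]
  it <- pt$inc[match(ids, pt$event_id)]; et <- pt$exc[match(ids, pt$event_id)]
  ic[is.na(ic)] <- 0; ec[is.na(ec)] <- 0; id_[is.na(id_)] <- 0
  ed[is.na(ed)] <- 0; it[is.na(it)] <- 0; et[is.na(et)] <- 0

  psi_c <- compute_psi(ic, ec)
  psi_d <- compute_psi(id_, ed)
  psi_t <- compute_psi(it, et)
  dpsi <- psi_d - psi_c
  dpsi_treat <- psi_t - psi_d

  pv <- mapply(test_event, ic, ec, id_, ed)
  padj <- adjust_pvalues(pv)

  res <- data.frame(
    event_id = ids, gene = gene,
    inc_control = ic, exc_control = ec,
    inc_disease = id_, exc_disease = ed,
    inc_treated = it, exc_treated = et,
    psi_control = psi_c, psi_disease = psi_d, psi_treated = psi_t,
    dpsi = dpsi, pvalue = pv, padj = padj,
    reads_a = ic + ec, reads_b = id_ + ed,
    dpsi_treated = dpsi_treat,
    stringsAsFactors = FALSE, row.names = NULL)
  res$passes_filter <- filter_events(res, min_dpsi = min_dpsi,
                                     min_reads = min_reads, alpha = alpha)
  res$reversed <- event_reversal(res$dpsi, res$dpsi_treated,
                                 min_move = min_move)
  res$psr <- percent_splicing_recovery(psi_c, psi_d, psi_t)
  class(res) <- c("splice_event_table", "data.frame")
  res
}

#' Summary counts for a splicing analysis
#'
#' The "N of M" statement: how many events passed the study filter and how
#' many of those reversed after treatment.
#'
#' @param table a `splice_event_table` from [analyze_splicing()].
#' @return list with `n_events`, `n_filtered`, `n_genes_filtered`,
#'   `n_reversed` (among filtered events).
#' @export
splicing_summary <- function(table) {
  stopifnot(inherits(table, "splice_event_table"))
  filt <- table[table$passes_filter, ]
  list(n_events = nrow(table),
       n_filtered = nrow(filt),
       n_genes_filtered = length(unique(filt$gene)),
       n_reversed = sum(filt$reversed, na.rm = TRUE))
}
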