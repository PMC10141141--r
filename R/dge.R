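#' Median-of-ratios size factors
#'
#' Computes one size factor per sample as the median, over genes expressed in
#' every sample, of the ratio of that sample's count to the gene's geometric
#' mean across samples. Factors are rescaled to have geometric mean 1, so
#' normalized counts stay on the raw-count scale. When no gene is positive in
#' every sample the estimator falls back to total-count ratios.
#'
#' @param x a [count_matrix()] or a numeric matrix of counts.
#' @return list with `size_factors` (named per sample) and `normalized`
#'   (counts divided column-wise by the size factors).
#' @export
normalize_counts <- function(x) {
  m <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  if (ncol(m) < 2) stop("need at least 2 samples to normalize")
  if (all(m == 0)) stop("all-zero count matrix")
  eligible <- rowSums(m > 0) == ncol(m)
  if (any(eligible)) {
    lm_ <- log(m[eligible, , drop = FALSE])
    geo <- rowMeans(lm_)
    sf <- apply(exp(lm_ - geo), 2, stats::median)
  } else {
    tot <- colSums(m)
    sf <- tot / exp(mean(log(tot)))
  }
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(m)
  list(size_factors = sf, normalized = sweep(m, 2, sf, "/"))
}

#' Per-gene negative-binomial dispersion
#'
#' Method-of-moments estimate from within-group residuals of size-factor
#' normalized counts, shrunk toward a smooth mean-dispersion trend. The raw
#' estimate for gene g is `(pooled within-group variance - mean) / mean^2`,
#' floored at `floor`; the trend is a robust lowess fit of the raw estimates
#' against log mean; the final value is a weighted average with weight
#' `df / (df + prior_df)` on the gene-wise estimate, where df is the residual
#' degrees of freedom (samples minus groups).
#'
#' @param x a [count_matrix()].
#' @param groups optional subset of group labels to use (default all).
#' @param prior_df prior degrees of freedom carried by the trend.
#' @param floor lower bound for dispersions.
#' @return named numeric vector of dispersions (one per gene), with the raw
#'   and trend values attached as attributes.
#' @export
estimate_dispersion <- function(x, groups = NULL, prior_df = 10,
                                floor = 1e-8) {
  stopifnot(inherits(x, "count_matrix"))
  design <- x$design
  if (!is.null(groups)) design <- design[design$group %in% groups, ]
  tab <- table(design$group)
  if (!any(tab >= 2))
    stop("dispersion estimation needs replicates: some group must have >= 2 samples")
  norm <- normalize_counts(x)$normalized[, design$sample, drop = FALSE]
  grp <- split(design$sample, design$group)

  ss <- 0; df <- 0; gmean <- 0
  for (s in grp) {
    sub <- norm[, s, drop = FALSE]
    mu <- rowMeans(sub)
    ss <- ss + rowSums((sub - mu)^2)
    df <- df + (length(s) - 1)
    gmean <- gmean + mu * length(s)
  }
  gmean <- gmean / nrow(design)
  v <- ss / df
  raw <- ifelse(gmean > 0, (v - gmean) / gmean^2, 0)
  raw <- pmax(raw, floor)

  ok <- gmean > 0
  if (sum(ok) >= 10) {
    fit <- stats::lowess(log(gmean[ok]), raw[ok], f = 0.5)
    trend <- pmax(stats::approx(fit$x, fit$y, xout = log(pmax(gmean, 1e-8)),
                                rule = 2, ties = mean)$y, floor)
  } else {
    trend <- rep(stats::median(raw), length(raw))
  }
  w <- df / (df + prior_df)
  disp <- pmax(w * raw + (1 - w) * trend, floor)
  names(disp) <- rownames(norm)
  attr(disp, "raw") <- raw
  attr(disp, "trend") <- trend
  disp
}

#' Differential expression between two groups
#'
#' Per-gene two-sided exact negative-binomial test conditional on the pooled
#' count, in the style of the classic exact test for count data: counts are
#' first equalized to a common library size via median-of-ratios size factors
#' and rounded to pseudo-counts, group sums are modeled as NB with the
#' estimated dispersion, and the two-sided p-value doubles the smaller
#' conditional tail (capped at 1). Fold changes are
#' `log2((meanB + c) / (meanA + c))` on normalized group means with
#' pseudo-count `c = 0.5`.
#'
#' Genes whose mean raw count across all samples falls below
#' `min_mean_count` are dropped before testing (recorded in the
#' `filtered_genes` attribute).
#'
#' @param x a [count_matrix()].
#' @param group_a reference group label.
#' @param group_b comparison group label (fold changes are B over A).
#' @param dispersion optional named dispersion vector (as from
#'   [estimate_dispersion()]); estimated from the two groups when missing.
#' @param alpha adjusted-p threshold for the altered flag.
#' @param lfc absolute log2-fold-change threshold for the altered flag.
#' @param min_mean_count low-expression filter on the mean raw count.
#' @return a `dge_result` data.frame with columns gene, mean_a, mean_b
#'   (normalized group means), log2fc, pvalue, padj, altered, direction.
#' @export
test_differential <- function(x, group_a, group_b, dispersion = NULL,
                              alpha = 0.05, lfc = 1, min_mean_count = 5) {
  stopifnot(inherits(x, "count_matrix"))
  for (g in c(group_a, group_b))
    if (!g %in% x$design$group) stop(sprintf("unknown group '%s'", g))
  sa <- group_samples(x, group_a)
  sb <- group_samples(x, group_b)
  if (length(sa) < 2 || length(sb) < 2)
    stop("both groups need >= 2 samples")

  keep <- rowMeans(x$counts) >= min_mean_count
  sub <- count_matrix(x$counts[keep, , drop = FALSE], x$design)
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(sub, groups = c(group_a, group_b))
  } else {
    if (is.null(names(dispersion))) stop("dispersion must be named by gene")
    dispersion <- dispersion[rownames(sub$counts)]
    if (anyNA(dispersion)) stop("dispersion missing for some tested genes")
  }

  norm <- normalize_counts(sub)
  pseudo <- round(norm$normalized)
  ya <- rowSums(pseudo[, sa, drop = FALSE])
  yb <- rowSums(pseudo[, sb, drop = FALSE])
  na <- length(sa); nb <- length(sb)

  pv <- nb_exact_pvalue(ya, yb, na, nb, pmax(dispersion, 1e-8))

  mean_a <- rowMeans(norm$normalized[, sa, drop = FALSE])
  mean_b <- rowMeans(norm$normalized[, sb, drop = FALSE])
  log2fc <- log2((mean_b + 0.5) / (mean_a + 0.5))
  padj <- adjust_pvalues(pv)
  altered <- padj < alpha & abs(log2fc) >= lfc
  direction <- ifelse(!altered, "none", ifelse(log2fc > 0, "up", "down"))

  res <- data.frame(gene = rownames(sub$counts),
                    mean_a = mean_a, mean_b = mean_b,
                    log2fc = log2fc, pvalue = pv, padj = padj,
                    altered = altered, direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "contrast") <- c(reference = group_a, comparison = group_b)
  attr(res, "thresholds") <- c(alpha = alpha, lfc = lfc)
  attr(res, "filtered_genes") <- rownames(x$counts)[!keep]
  class(res) <- c("dge_result", "data.frame")
  res
}

# Two-sided exact NB p-values for group sums ya ~ NB(na*mu, phi/na),
# yb ~ NB(nb*mu, phi/nb), conditional on t = ya + yb, null mean
# mu = t / (na + nb) per pseudo-library. Doubles the smaller tail; the
# observed outcome is counted in both tails, so p is capped at 1.
nb_exact_pvalue <- function(ya, yb, na, nb, phi) {
  ng <- length(ya)
  p <- numeric(ng)
  for (i in seq_len(ng)) {
    t <- ya[i] + yb[i]
    if (t == 0) { p[i] <- 1; next }
    mu <- t / (na + nb)
    mua <- na * mu; mub <- nb * mu
    sza <- na / phi[i]; szb <- nb / phi[i]
    # support window: outcomes outside carry negligible mass
    lo <- max(0, stats::qnbinom(1e-14, mu = mua, size = sza),
              t - stats::qnbinom(1e-14, mu = mub, size = szb,
                                 lower.tail = FALSE))
    hi <- min(t, stats::qnbinom(1e-14, mu = mua, size = sza,
                                lower.tail = FALSE),
              t - stats::qnbinom(1e-14, mu = mub, size = szb))
    lo <- min(lo, ya[i]); hi <- max(hi, ya[i])
    a <- lo:hi
    logf <- stats::dnbinom(a, mu = mua, size = sza, log = TRUE) +
      stats::dnbinom(t - a, mu = mub, size = szb, log = TRUE)
    f <- exp(logf - max(logf))
    f <- f / sum(f)
    idx <- ya[i] - lo + 1
    lower <- sum(f[seq_len(idx)])
    upper <- sum(f[idx:length(f)])
    p[i] <- min(1, 2 * min(lower, upper))
  }
  p
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Validating wrapper around the BH step-up procedure: rejects missing or
#' out-of-range inputs, returns monotone adjusted values capped at 1.
#'
#' @param p numeric p-values in \[0, 1\].
#' @return adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p)) stop("p-values must not contain NA/NaN")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Altered-gene calls at the study thresholds
#'
#' A gene is called altered when its BH-adjusted p-value is below `alpha`
#' and its |log2 fold change| is at least `lfc` (threshold inclusive).
#'
#' @param dge a `dge_result` from [test_differential()].
#' @param alpha adjusted-p threshold (default 0.05).
#' @param lfc absolute log2-fold-change threshold (default 1).
#' @return character vector of altered gene ids.
#' @export
call_altered <- function(dge, alpha = 0.05, lfc = 1) {
  stopifnot(inherits(dge, "dge_result"), alpha > 0, lfc > 0)
  dge$gene[dge$padj < alpha & abs(dge$log2fc) >= lfc]
}

#' Write / read a DGE table as TSV
#' @param dge a `dge_result`.
#' @param path file path.
#' @return `write_dge_table` returns the path invisibly; `read_dge_table`
#'   returns a `dge_result`.
#' @export
write_dge_table <- function(dge, path) {
  utils::write.table(as.data.frame(dge), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_dge_table
#' @export
read_dge_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene", "log2fc", "pvalue", "padj", "altered", "direction")
  if (!all(req %in% names(d)))
    stop("not a DGE table: missing columns")
  class(d) <- c("dge_result", "data.frame")
  d
}
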