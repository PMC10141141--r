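#' Gene-by-sample count matrix with a group design
#'
#' Light container pairing an integer count matrix with a sample-to-group
#' design, validated on construction. This is the pipeline's main input:
#' RSEM-style expected counts rounded to integers, one row per gene, one
#' column per sample.
#'
#' @param counts numeric matrix (genes x samples) of non-negative integral
#'   counts with unique row and column names.
#' @param design data.frame with columns `sample` and `group`; every column of
#'   `counts` must appear exactly once.
#' @return an object of class `count_matrix`: a list with `counts` (integer
#'   matrix) and `design`.
#' @export
count_matrix <- function(counts, design) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts must have unique gene row names")
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stop("counts must have unique sample column names")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integral (round RSEM expected counts first)")
  storage.mode(counts) <- "integer"
  if (!all(c("sample", "group") %in% names(design)))
    stop("design needs 'sample' and 'group' columns")
  design <- design[, c("sample", "group")]
  design$sample <- as.character(design$sample)
  design$group <- as.character(design$group)
  if (anyDuplicated(design$sample)) stop("duplicate samples in design")
  if (!setequal(design$sample, colnames(counts)) ||
      length(design$sample) != ncol(counts))
    stop("design samples must match count matrix columns exactly")
  design <- design[match(colnames(counts), design$sample), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(counts = counts, design = design), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(table(x$design$group))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Samples belonging to a group
#' @param x a `count_matrix`.
#' @param group group label present in the design.
#' @return character vector of sample ids.
#' @export
group_samples <- function(x, group) {
  stopifnot(inherits(x, "count_matrix"))
  s <- x$design$sample[x$design$group == group]
  if (length(s) == 0) stop(sprintf("group '%s' has no samples", group))
  s
}

#' Write / read a count matrix as TSV
#'
#' `write_count_matrix` writes two tab-delimited files: the counts (first
#' column `gene_id`, then one column per sample) and the two-column design
#' (`sample`, `group`). `read_count_matrix` is its inverse.
#'
#' @param x a `count_matrix`.
#' @param counts_path,design_path file paths.
#' @return `write_count_matrix` returns the paths invisibly;
#'   `read_count_matrix` returns a `count_matrix`.
#' @export
write_count_matrix <- function(x, counts_path, design_path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$design, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts = counts_path, design = design_path))
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(counts_path, design_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  count_matrix(m, design)
}
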