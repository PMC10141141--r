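# Small in-code fixtures shared across test files.

# A tiny two-group count matrix with known structure.
toy_count_matrix <- function(n_genes = 50, n = 4, seed = 1,
                             groups = c("CNT", "DIS")) {
  set.seed(seed)
  mu <- exp(rnorm(n_genes, 4, 1))
  counts <- sapply(seq_len(length(groups) * n), function(j)
    rnbinom(n_genes, mu = mu, size = 10))
  rownames(counts) <- sprintf("g%03d", seq_len(n_genes))
  colnames(counts) <- paste0(rep(groups, each = n), "_", seq_len(n))
  count_matrix(counts, data.frame(sample = colnames(counts),
                                  group = rep(groups, each = n)))
}

# Independent median-of-ratios oracle: plain double loop, no shared code.
size_factors_oracle <- function(m) {
  keep <- apply(m > 0, 1, all)
  gm <- apply(m[keep, , drop = FALSE], 1, function(r) exp(mean(log(r))))
  sf <- numeric(ncol(m))
  for (j in seq_len(ncol(m)))
    sf[j] <- median(m[keep, j] / gm)
  sf / exp(mean(log(sf)))
}

# Independent BH step-up enumeration.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- Inf
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- min(prev, 1)
  }
  adj
}
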