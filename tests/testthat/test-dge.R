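test_that("size factors recover known scalings and match the brute-force oracle", {
  cm <- toy_count_matrix(n_genes = 60, seed = 2)
  m <- cm$counts
  # doubling one sample doubles its factor relative to the rest
  m2 <- m
  m2[, 1] <- m2[, 1] * 2L
  sf <- normalize_counts(m2)$size_factors
  expect_equal(unname(sf[1] / sf[2]),
               2 * unname(normalize_counts(m)$size_factors[1] /
                            normalize_counts(m)$size_factors[2]),
               tolerance = 1e-10)
  # identical samples: all factors equal
  ident <- matrix(rep(m[, 1], 4), ncol = 4,
                  dimnames = list(rownames(m), paste0("s", 1:4)))
  expect_equal(unname(normalize_counts(ident)$size_factors), rep(1, 4))
  # random matrix equals the independent oracle
  expect_equal(unname(normalize_counts(m)$size_factors),
               size_factors_oracle(m), tolerance = 1e-12)
  expect_error(normalize_counts(matrix(0, 3, 3,
    dimnames = list(letters[1:3], LETTERS[1:3]))), "all-zero")
})

test_that("fallback size factors equal total-count ratios when no gene is always expressed", {
  m <- matrix(c(10, 0, 0, 30,
                0, 20, 40, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), paste0("s", 1:4)))
  sf <- normalize_counts(m)$size_factors
  tot <- colSums(m)
  expect_equal(unname(sf), unname(tot / exp(mean(log(tot)))))
})

test_that("dispersion estimates are calibrated at phi = 0.2 and floor at constants", {
  cfg <- sim_config(n_genes = 2000, seed = 4, dispersion = 0.2,
                    treatments = list(arm = list(recovery_fraction = 1,
                                                 off_target_rate = 0,
                                                 antagomir_like = FALSE)))
  sim <- simulate_counts(cfg)
  disp <- estimate_dispersion(sim$counts)
  expect_equal(median(disp), 0.2, tolerance = 0.25)  # within 0.2 +/- 0.05
  # Poisson data: dispersions collapse toward zero
  cfgp <- sim_config(n_genes = 1000, n_samples_per_group = 20, seed = 4,
                     dispersion = 0,
                     treatments = list(arm = list(recovery_fraction = 1,
                                                  off_target_rate = 0,
                                                  antagomir_like = FALSE)))
  dp <- estimate_dispersion(simulate_counts(cfgp)$counts)
  expect_lt(median(dp), 0.02)
  # constant gene sits at the floor
  m <- matrix(5L, 10, 4, dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  m[1, ] <- c(5L, 9L, 2L, 7L)  # one varying gene so lowess has signal
  cm <- count_matrix(m, data.frame(sample = paste0("s", 1:4),
                                   group = rep("A", 4)))
  d <- estimate_dispersion(cm, prior_df = 0)
  expect_equal(unname(attr(d, "raw")[2]), 1e-8)
  expect_error(estimate_dispersion(count_matrix(m[, 1, drop = FALSE],
    data.frame(sample = "s1", group = "A"))), "replicates")
})

test_that("identical groups give log2fc 0 and p-values near 1", {
  cm <- toy_count_matrix(n_genes = 40, seed = 6)
  m <- cm$counts[, 1:4]
  dup <- cbind(m, m)
  colnames(dup) <- paste0("s", 1:8)
  cmd <- count_matrix(dup, data.frame(sample = colnames(dup),
                                      group = rep(c("A", "B"), each = 4)))
  d <- test_differential(cmd, "A", "B", min_mean_count = 0)
  expect_equal(d$log2fc, rep(0, nrow(d)))
  expect_true(all(d$pvalue > 0.99))
})

test_that("swapping groups negates log2fc and preserves p-values", {
  sim <- simulate_counts(sim_config(n_genes = 150, seed = 9))
  d1 <- test_differential(sim$counts, "CNT", "DIS")
  d2 <- test_differential(sim$counts, "DIS", "CNT")
  expect_equal(d1$log2fc, -d2$log2fc, tolerance = 1e-10)
  expect_equal(d1$pvalue, d2$pvalue, tolerance = 1e-10)
})

test_that("BH wrapper matches the closed form and the step-up enumeration oracle", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(adjust_pvalues(0.2), 0.2)
  set.seed(10)
  p <- runif(100)
  expect_equal(adjust_pvalues(p), bh_oracle(p), tolerance = 1e-12)
  expect_true(all(adjust_pvalues(p) >= p))
  expect_error(adjust_pvalues(c(0.1, NA)), "NA")
  expect_error(adjust_pvalues(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("altered calls apply both thresholds, inclusively on |log2fc|", {
  d <- structure(data.frame(gene = c("a", "b", "c", "d"),
                            mean_a = 1, mean_b = 1,
                            log2fc = c(1.2, 0.9, -1.0, 2),
                            pvalue = c(0.001, 0.001, 0.001, 0.2),
                            padj = c(0.04, 0.04, 0.04, 0.4),
                            altered = NA, direction = NA),
                 class = c("dge_result", "data.frame"))
  expect_setequal(call_altered(d), c("a", "c"))
})

test_that("exact NB test agrees with an independent exact-test implementation", {
  skip_if_not_installed("edgeR")
  sim <- simulate_counts(sim_config(n_genes = 300, seed = 12))
  d <- test_differential(sim$counts, "CNT", "DIS")
  sub <- sim$counts$counts[d$gene, c(group_samples(sim$counts, "CNT"),
                                     group_samples(sim$counts, "DIS"))]
  y <- edgeR::DGEList(sub, group = rep(c("CNT", "DIS"), each = 4))
  y <- edgeR::calcNormFactors(y)
  y <- edgeR::estimateDisp(y)
  et <- edgeR::exactTest(y)
  # same machinery family: rankings should agree strongly
  expect_gt(cor(d$pvalue, et$table$PValue, method = "spearman"), 0.9)
  expect_gt(cor(d$log2fc, et$table$logFC), 0.95)
})

test_that("one sample's integer rescaling is absorbed by its size factor", {
  sim <- simulate_counts(sim_config(n_genes = 200, seed = 14))
  cm <- sim$counts
  m2 <- cm$counts
  m2[, 1] <- m2[, 1] * 3L
  cm2 <- count_matrix(m2, cm$design)
  f1 <- normalize_counts(cm)$size_factors
  f2 <- normalize_counts(cm2)$size_factors
  expect_equal(unname((f2 / f1)[1] / (f2 / f1)[2]), 3, tolerance = 0.05)
  d1 <- test_differential(cm, "CNT", "DIS")
  d2 <- test_differential(cm2, "CNT", "DIS")
  expect_equal(d1$log2fc, d2$log2fc, tolerance = 0.2)
})
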