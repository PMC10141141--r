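test_that("percent recovery reproduces the printed formula and endpoints", {
  expect_equal(percent_recovery(200, 100, 100), 0)    # treated at disease
  expect_equal(percent_recovery(200, 100, 200), 100)  # treated at control
  expect_equal(percent_recovery(200, 100, 180), 80)
  expect_equal(percent_recovery(100, 200, 150), 50)   # works for up-genes too
  expect_error(percent_recovery(-1, 2, 3), "non-negative")
})

test_that("percent recovery guards the unstable denominator and is scale invariant", {
  expect_true(is.na(percent_recovery(100, 100.5, 120)))
  expect_true(is.na(percent_recovery(100, 100, 120)))
  # affine invariance in the overall scale
  set.seed(3)
  for (i in 1:20) {
    mc <- runif(1, 50, 500); md <- runif(1, 50, 500); mt <- runif(1, 50, 500)
    k <- runif(1, 0.1, 10)
    if (abs(mc - md) >= 1 && abs(k * (mc - md)) >= 1)
      expect_equal(percent_recovery(mc, md, mt),
                   percent_recovery(k * mc, k * md, k * mt))
  }
})

test_that("recovery categories partition the line and match interval arithmetic", {
  expect_equal(classify_recovery(5), "unrecovered")
  expect_equal(classify_recovery(-30), "unrecovered")
  expect_equal(classify_recovery(80), "total")
  expect_equal(classify_recovery(c(10, 50, 150, 150.0001)),
               c("partial", "total", "total", "over"))
  expect_equal(classify_recovery(NA), "undefined")
  grid <- seq(-200, 300, by = 0.125)
  got <- classify_recovery(grid)
  oracle <- ifelse(grid < 10, "unrecovered",
            ifelse(grid < 50, "partial",
            ifelse(grid <= 150, "total", "over")))
  expect_identical(got, oracle)
  expect_true(all(table(got) > 0))  # every class hit on the grid
})

test_that("intersection ratio is the Jaccard index with the empty-set convention", {
  expect_equal(intersection_ratio(c("a", "b"), c("a", "b")), 1)
  expect_equal(intersection_ratio(c("a"), c("b")), 0)
  expect_equal(intersection_ratio(letters[1:10], letters[6:20]),
               5 / 20)
  expect_warning(r <- intersection_ratio(character(0), character(0)),
                 "empty")
  expect_equal(r, 0)
  # symmetry
  expect_equal(intersection_ratio(letters[1:7], letters[5:9]),
               intersection_ratio(letters[5:9], letters[1:7]))
})

test_that("disease gene calling and reversals follow directions", {
  sim <- simulate_counts(sim_config(n_genes = 800, seed = 21,
    effect_log2_range = c(2, 2.5),
    treatments = list(block = list(recovery_fraction = 0.9,
                                   off_target_rate = 0,
                                   antagomir_like = FALSE))))
  dge_dis <- test_differential(sim$counts, "CNT", "DIS")
  ds <- disease_related_genes(dge_dis)
  truegenes <- sim$truth$gene_ids[sim$truth$is_disease_gene]
  expect_gt(mean(truegenes %in% ds$gene), 0.85)
  # directions match the simulated effect signs
  idx <- match(ds$gene, sim$truth$gene_ids)
  hit <- ds$gene %in% truegenes
  expect_true(all((ds$direction == "up") ==
                    (sim$truth$delta_log2[idx] > 0) | !hit))

  dge_tr <- test_differential(sim$counts, "DIS", "block")
  rv <- reversal_calls(ds, dge_tr)
  expect_true(all(rv$reversals %in% ds$gene))
  expect_gt(rv$reversal_fraction, 0.9)  # clean arm: alterations are rescues
  expect_equal(rv$missing_genes, character(0))
})

test_that("a gene pushed further in the disease direction is not a reversal", {
  ds <- data.frame(gene = c("g1", "g2"), direction = c("up", "up"))
  dge <- structure(data.frame(gene = c("g1", "g2"), mean_a = 1, mean_b = 1,
                              log2fc = c(-2, 2), pvalue = 0.001,
                              padj = c(0.01, 0.01), altered = TRUE,
                              direction = c("down", "up")),
                   class = c("dge_result", "data.frame"))
  rv <- reversal_calls(ds, dge)
  expect_equal(rv$reversals, "g1")
})

test_that("recovery tables and summaries count categories over disease genes", {
  sim <- simulate_counts(sim_config(n_genes = 500, seed = 31,
    treatments = list(
      a = list(recovery_fraction = 0.8, off_target_rate = 0,
               antagomir_like = FALSE),
      b = list(recovery_fraction = 0.8, off_target_rate = 0,
               antagomir_like = FALSE))))
  dge_dis <- test_differential(sim$counts, "CNT", "DIS")
  ds <- disease_related_genes(dge_dis)
  ta <- build_recovery_table(sim$counts, "CNT", "DIS", "a", disease_set = ds)
  tb <- build_recovery_table(sim$counts, "CNT", "DIS", "b", disease_set = ds)
  expect_s3_class(ta, "recovery_table")
  expect_identical(ta$category, classify_recovery(ta$pct_recovery))
  s <- recovery_summary(list(a = ta, b = tb))
  expect_equal(sum(s$category_counts["a", ]), nrow(ds))
  # single-gene sanity: an 80% gene lands in 'total'
  one <- ta[which(ta$is_disease_gene)[1], , drop = FALSE]
  expect_equal(unname(rowSums(s$category_counts)), rep(nrow(ds), 2))
  # same table twice: intersection ratio of recovered sets is 1
  s2 <- recovery_summary(list(x = ta, y = ta))
  if (length(s2$recovered_sets$x) > 0)
    expect_equal(unname(s2$intersection_ratios), 1)
  # mismatched universes error
  ta_sub <- ta[-1, ]
  class(ta_sub) <- class(ta)
  expect_error(recovery_summary(list(a = ta_sub, b = tb)), "universe")
})

test_that("hard-target report flags missing targets and errors on empty overlap", {
  d <- structure(data.frame(gene = c("g1", "g2"), mean_a = 1, mean_b = 1,
                            log2fc = c(1.5, 0.2), pvalue = c(0.001, 0.6),
                            padj = c(0.01, 0.8), altered = c(TRUE, FALSE),
                            direction = c("up", "none")),
                 class = c("dge_result", "data.frame"))
  rep <- hard_target_report(list(arm = d), c("g1", "g2", "gX"))
  expect_equal(rep$missing_targets, "gX")
  expect_equal(unname(rep$altered_counts), 1)
  expect_equal(rep$log2fc["g1", "arm"], 1.5)
  expect_error(hard_target_report(list(arm = d), c("zz")), "no hard target")
})
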