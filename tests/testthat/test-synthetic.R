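test_that("sim_config validates its inputs", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(frac_disease_genes = 1), "frac_disease_genes")
  expect_error(sim_config(treatments = list(
    a = list(recovery_fraction = 2.5))), "recovery_fraction")
  expect_error(sim_config(treatments = list(
    a = list(recovery_fraction = 1, off_target_rate = 1))),
    "off_target_rate")
  expect_s3_class(sim_config(n_genes = 10), "sim_config")
})

test_that("identical seeds reproduce counts byte-for-byte, different seeds differ", {
  cfg1 <- sim_config(n_genes = 100, seed = 7)
  cfg2 <- sim_config(n_genes = 100, seed = 8)
  a <- simulate_counts(cfg1)
  b <- simulate_counts(cfg1)
  c <- simulate_counts(cfg2)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$counts$counts, c$counts$counts))
})

test_that("truth aligns with the matrix and non-disease genes carry no effect", {
  sim <- simulate_counts(sim_config(n_genes = 300, seed = 3))
  expect_identical(sim$truth$gene_ids, rownames(sim$counts$counts))
  expect_true(all(sim$truth$delta_log2[!sim$truth$is_disease_gene] == 0))
  expect_true(all(sim$truth$delta_log2[sim$truth$is_disease_gene] != 0))
  # off-targets only in antagomiR-like arms
  expect_true(all(!sim$truth$arms$blockmir$is_off_target))
  expect_equal(sim$truth$arms$blockmir$true_recovery_pct[
    sim$truth$is_disease_gene], rep(80, sum(sim$truth$is_disease_gene)))
})

test_that("recovery-fraction endpoints: rho = 1 matches control, rho = 0 matches disease", {
  cfg <- sim_config(
    n_genes = 400, n_samples_per_group = 50, seed = 5,
    dispersion = 0.001, baseline_mean_log_params = c(7, 0.3),
    treatments = list(
      full = list(recovery_fraction = 1, off_target_rate = 0,
                  antagomir_like = FALSE),
      none = list(recovery_fraction = 0, off_target_rate = 0,
                  antagomir_like = FALSE)))
  sim <- simulate_counts(cfg)
  cm <- sim$counts$counts
  dis <- sim$truth$is_disease_gene
  g <- function(p) rowMeans(cm[, grepl(p, colnames(cm)), drop = FALSE])
  # rho = 1: treated means track control means on disease genes
  expect_lt(median(abs(log2(g("^full") / g("^CNT"))[dis])), 0.1)
  # rho = 0: treated means track disease means
  expect_lt(median(abs(log2(g("^none") / g("^DIS"))[dis])), 0.1)
})

test_that("generated counts match NB mean/variance moments", {
  n <- 10000
  set.seed(99)
  mu <- 50; phi <- 0.2
  x <- txrecovery:::rnbinom_md(n, rep(mu, n), rep(phi, n))
  expect_equal(mean(x), mu, tolerance = 0.05)
  expect_equal(var(x), mu + phi * mu^2, tolerance = 0.1)
  y <- txrecovery:::rnbinom_md(n, rep(mu, n), rep(0, n))  # Poisson limit
  expect_equal(var(y), mu, tolerance = 0.1)
})

test_that("splice-event generator respects PSI endpoints and seeds", {
  tp <- cbind(CNT = c(100, 50, 0), DIS = c(100, 50, 0))
  sim <- simulate_splice_events(tp, n_samples_per_group = 2,
                                coverage_mean = 50, seed = 2)
  ev <- sim$events
  expect_true(all(ev$exclusion[ev$event_id == "event0001"] == 0))
  expect_true(all(ev$inclusion[ev$event_id == "event0003"] == 0))
  sim2 <- simulate_splice_events(tp, n_samples_per_group = 2,
                                 coverage_mean = 50, seed = 2)
  expect_identical(sim$events, sim2$events)
  expect_error(simulate_splice_events(cbind(A = 101)), "PSI")
  # law of large numbers at huge coverage
  big <- simulate_splice_events(cbind(A = 50, B = 50),
                                n_samples_per_group = 1,
                                coverage_mean = 2e5, seed = 3)$events
  expect_equal(compute_psi(big$inclusion, big$exclusion),
               rep(50, 2), tolerance = 0.01)
})

test_that("dose-response generator hits the 4PL midpoint and asymptotes", {
  d <- simulate_dose_response(150, hill = 1.5, noise_sd = 0,
                              doses = c(1e-6, 150, 1e9), n_replicates = 1)
  expect_equal(d$response[d$dose_nm == 150], 50)
  expect_lt(d$response[d$dose_nm == 1e-6], 1e-3)
  expect_gt(d$response[d$dose_nm == 1e9], 99.99)
  expect_error(simulate_dose_response(-5), "positive")
})

test_that("qPCR generator: zero noise and equal expression give ddCt 0; 2-fold gives RQ 2", {
  rec <- simulate_qpcr(c(ctl = 0, trt = 0), noise_sd = 0, seed = 1)
  rq <- relative_expression_ddct(rec, "ctl")
  expect_equal(rq$rq, c(1, 1))
  rec2 <- simulate_qpcr(c(ctl = 0, trt = 1), noise_sd = 0, seed = 1)
  rq2 <- relative_expression_ddct(rec2, "ctl")
  expect_equal(rq2$rq[rq2$group == "trt"], 2)
})
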