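#' Simulation configuration for the four-group rescue design
#'
#' Builds a validated configuration for [simulate_counts()], describing a
#' control / disease / treated RNA-seq experiment with known ground truth.
#' The defaults emulate a myotonic-dystrophy-like cell study: a healthy
#' control group, a disease group in which a subset of genes is dysregulated,
#' and one or more antisense-oligonucleotide treatment arms that restore a
#' known fraction of the disease effect. Treatment arms flagged
#' "antagomiR-like" additionally perturb a random off-target gene set,
#' mirroring the broader transcriptomic footprint of miRNA-directed (rather
#' than binding-site-directed) oligonucleotides.
#'
#' @param n_genes number of genes to simulate.
#' @param n_samples_per_group biological replicates per group.
#' @param treatments named list describing each treatment arm; each element is
#'   a list with `recovery_fraction` (rho in \[0, 2\]: the fraction of the
#'   disease shift undone, on the linear count scale), `off_target_rate`
#'   (fraction of genes perturbed independently of disease status, in
#'   \[0, 1)), and `antagomir_like` (logical; off-target perturbations are
#'   applied only when `TRUE`).
#' @param frac_disease_genes fraction of genes dysregulated in disease, in (0, 1).
#' @param effect_log2_range range (low, high) of |log2 effect| for disease genes.
#' @param off_target_log2_sd standard deviation of the log2 perturbation
#'   applied to off-target genes in antagomiR-like arms.
#' @param off_target_log2_magnitude optional fixed |log2| effect for
#'   off-target genes (random sign); overrides the Gaussian draw when set,
#'   for simulations that pin the off-target effect size.
#' @param baseline_mean_log_params location and scale (natural-log scale) of
#'   the log-normal distribution of baseline gene means.
#' @param dispersion negative-binomial dispersion phi (variance = mu + phi*mu^2);
#'   a single value applied to every gene, or a vector of length `n_genes`.
#' @param seed integer seed fixing every random draw.
#'
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_samples_per_group = 4,
                       treatments = list(
                         blockmir  = list(recovery_fraction = 0.8,
                                          off_target_rate   = 0,
                                          antagomir_like    = FALSE),
                         antagomir = list(recovery_fraction = 0.8,
                                          off_target_rate   = 0.05,
                                          antagomir_like    = TRUE)
                       ),
                       frac_disease_genes = 0.1,
                       effect_log2_range = c(1, 2.5),
                       off_target_log2_sd = 1,
                       off_target_log2_magnitude = NULL,
                       baseline_mean_log_params = c(location = 4, scale = 1.5),
                       dispersion = 0.1,
                       seed = 1L) {
  stopifnot(length(n_genes) == 1, n_genes >= 1,
            length(n_samples_per_group) == 1, n_samples_per_group >= 1)
  if (!is.list(treatments) || length(treatments) < 1 ||
      is.null(names(treatments)) || anyDuplicated(names(treatments)))
    stop("'treatments' must be a non-empty uniquely named list")
  for (nm in names(treatments)) {
    tr <- treatments[[nm]]
    rho <- tr$recovery_fraction
    if (is.null(rho) || rho < 0 || rho > 2)
      stop(sprintf("treatment '%s': recovery_fraction must be in [0, 2]", nm))
    otr <- tr$off_target_rate %||% 0
    if (otr < 0 || otr >= 1)
      stop(sprintf("treatment '%s': off_target_rate must be in [0, 1)", nm))
    treatments[[nm]]$off_target_rate <- otr
    treatments[[nm]]$antagomir_like <- isTRUE(tr$antagomir_like)
  }
  if (frac_disease_genes <= 0 || frac_disease_genes >= 1)
    stop("frac_disease_genes must be in (0, 1)")
  stopifnot(length(effect_log2_range) == 2, all(effect_log2_range > 0),
            effect_log2_range[1] <= effect_log2_range[2],
            off_target_log2_sd > 0,
            is.null(off_target_log2_magnitude) ||
              off_target_log2_magnitude > 0,
            length(baseline_mean_log_params) == 2,
            baseline_mean_log_params[2] >= 0,
            all(dispersion >= 0),
            length(dispersion) %in% c(1L, as.integer(n_genes)))
  structure(list(
    n_genes = as.integer(n_genes),
    n_samples_per_group = as.integer(n_samples_per_group),
    treatments = treatments,
    frac_disease_genes = frac_disease_genes,
    effect_log2_range = effect_log2_range,
    off_target_log2_sd = off_target_log2_sd,
    off_target_log2_magnitude = off_target_log2_magnitude,
    baseline_mean_log_params = unname(baseline_mean_log_params),
    dispersion = dispersion,
    seed = as.integer(seed)
  ), class = "sim_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a count matrix with ground truth
#'
#' Draws gene-level counts for a control group ("CNT"), a disease group
#' ("DIS"), and each treatment arm from a negative binomial with
#' variance mu + phi*mu^2. For disease genes the disease-group mean is
#' `mu_ctl * 2^delta_g`; a treatment arm's mean interpolates linearly between
#' the disease and control means, `mu_dis + rho * (mu_ctl - mu_dis)`, so that
#' the downstream percent-recovery statistic has expectation `100 * rho`.
#' Off-target genes in antagomiR-like arms are further multiplied by
#' `2^epsilon`, epsilon ~ Normal(0, off_target_log2_sd).
#'
#' @param config a [sim_config()].
#' @return a list with `counts` (a `count_matrix`; see [count_matrix()]) and
#'   `truth`, a list holding per-gene truth (`is_disease_gene`, `delta_log2`,
#'   baseline/disease means) and per-arm truth (`is_off_target`,
#'   `off_target_log2`, `true_recovery_pct`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  n  <- config$n_samples_per_group

  gene_ids <- sprintf("gene%04d", seq_len(ng))
  mu_ctl <- exp(rnorm(ng, config$baseline_mean_log_params[1],
                      config$baseline_mean_log_params[2]))

  n_dis <- max(1L, round(config$frac_disease_genes * ng))
  is_disease <- rep(FALSE, ng)
  is_disease[sample.int(ng, n_dis)] <- TRUE
  delta <- numeric(ng)
  delta[is_disease] <- sample(c(-1, 1), n_dis, replace = TRUE) *
    runif(n_dis, config$effect_log2_range[1], config$effect_log2_range[2])
  mu_dis <- mu_ctl * 2^delta

  phi <- rep_len(config$dispersion, ng)

  groups <- c("CNT", "DIS", names(config$treatments))
  group_means <- list(CNT = mu_ctl, DIS = mu_dis)
  arm_truth <- list()
  for (nm in names(config$treatments)) {
    tr <- config$treatments[[nm]]
    mu_tr <- mu_dis + tr$recovery_fraction * (mu_ctl - mu_dis)
    is_off <- rep(FALSE, ng)
    eps <- numeric(ng)
    if (tr$antagomir_like && tr$off_target_rate > 0) {
      is_off <- runif(ng) < tr$off_target_rate
      eps[is_off] <- if (is.null(config$off_target_log2_magnitude)) {
        rnorm(sum(is_off), 0, config$off_target_log2_sd)
      } else {
        sample(c(-1, 1), sum(is_off), replace = TRUE) *
          config$off_target_log2_magnitude
      }
      mu_tr <- mu_tr * 2^eps
    }
    group_means[[nm]] <- mu_tr
    arm_truth[[nm]] <- list(
      recovery_fraction = tr$recovery_fraction,
      antagomir_like = tr$antagomir_like,
      is_off_target = is_off,
      off_target_log2 = eps,
      true_recovery_pct = ifelse(is_disease, 100 * tr$recovery_fraction, 0)
    )
  }

  counts <- matrix(0L, nrow = ng, ncol = length(groups) * n)
  sample_ids <- character(ncol(counts))
  design_group <- character(ncol(counts))
  col <- 0L
  for (g in groups) {
    mu <- group_means[[g]]
    for (j in seq_len(n)) {
      col <- col + 1L
      sample_ids[col] <- sprintf("%s_%d", g, j)
      design_group[col] <- g
      counts[, col] <- rnbinom_md(ng, mu = mu, phi = phi)
    }
  }
  rownames(counts) <- gene_ids
  colnames(counts) <- sample_ids

  cm <- count_matrix(counts, data.frame(sample = sample_ids,
                                        group = design_group,
                                        stringsAsFactors = FALSE))
  truth <- list(
    gene_ids = gene_ids,
    is_disease_gene = is_disease,
    delta_log2 = delta,
    mu_control = mu_ctl,
    mu_disease = mu_dis,
    arms = arm_truth,
    control_group = "CNT",
    disease_group = "DIS"
  )
  list(counts = cm, truth = truth)
}

# NB draw under the (mean, dispersion) parameterization; phi = 0 is Poisson.
rnbinom_md <- function(n, mu, phi) {
  out <- integer(n)
  pois <- phi <= 0
  if (any(pois)) out[pois] <- rpois(sum(pois), mu[pois])
  if (any(!pois)) out[!pois] <- rnbinom(sum(!pois), mu = mu[!pois],
                                        size = 1 / phi[!pois])
  out
}

#' Simulate a splicing-event table with known PSI per group
#'
#' For each event and sample, inclusion reads are Binomial(coverage, PSI/100)
#' with per-sample coverage drawn as Poisson(coverage_mean); exclusion reads
#' are the remainder.
#'
#' @param true_psi numeric matrix (events x groups) of true percent-spliced-in
#'   values in \[0, 100\]; column names are group labels.
#' @param n_samples_per_group replicates per group.
#' @param coverage_mean Poisson mean of informative reads per event per sample.
#' @param seed integer seed.
#' @return list with `events` (long-format data.frame: event_id, gene, sample,
#'   group, inclusion, exclusion) and `truth` (the `true_psi` matrix).
#' @export
simulate_splice_events <- function(true_psi, n_samples_per_group = 4,
                                   coverage_mean = 100, seed = 1L) {
  true_psi <- as.matrix(true_psi)
  if (any(true_psi < 0 | true_psi > 100))
    stop("true PSI values must lie in [0, 100]")
  if (is.null(colnames(true_psi))) stop("true_psi needs group column names")
  set.seed(seed)
  ne <- nrow(true_psi)
  event_ids <- rownames(true_psi) %||% sprintf("event%04d", seq_len(ne))
  genes <- sprintf("gene%04d", seq_len(ne))
  rows <- list()
  for (g in colnames(true_psi)) {
    for (j in seq_len(n_samples_per_group)) {
      cov <- rpois(ne, coverage_mean)
      inc <- rbinom(ne, cov, true_psi[, g] / 100)
      rows[[length(rows) + 1L]] <- data.frame(
        event_id = event_ids, gene = genes,
        sample = sprintf("%s_%d", g, j), group = g,
        inclusion = inc, exclusion = cov - inc,
        stringsAsFactors = FALSE)
    }
  }
  list(events = do.call(rbind, rows), truth = true_psi)
}

#' Simulate a dose-response viability table
#'
#' Responses follow a four-parameter logistic in log10 dose with bottom 0 and
#' top 100, plus Gaussian noise.
#'
#' @param true_tc50 true midpoint concentration (nM), > 0.
#' @param hill hill slope.
#' @param noise_sd response noise standard deviation (percentage points).
#' @param doses dose levels in nM; defaults to the six-point screen
#'   2 nM - 5 uM.
#' @param n_replicates replicates per dose.
#' @param seed integer seed.
#' @return data.frame with columns dose_nm, replicate, response.
#' @export
simulate_dose_response <- function(true_tc50, hill = 1, noise_sd = 5,
                                   doses = c(2, 10, 50, 200, 1000, 5000),
                                   n_replicates = 3, seed = 1L) {
  if (true_tc50 <= 0) stop("true_tc50 must be positive")
  if (any(doses <= 0)) stop("doses must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  grid <- expand.grid(dose_nm = doses, replicate = seq_len(n_replicates))
  mu <- four_pl(log10(grid$dose_nm), bottom = 0, top = 100,
                log_tc50 = log10(true_tc50), hill = hill)
  grid$response <- mu + rnorm(nrow(grid), 0, noise_sd)
  grid[order(grid$dose_nm, grid$replicate), , drop = FALSE]
}

#' Simulate a qPCR Ct table
#'
#' Target Ct values encode true log2 expression differences relative to a
#' calibrator group (one extra cycle = half the expression), plus Gaussian
#' technical noise on both channels.
#'
#' @param group_log2_expr named numeric vector of true log2 expression
#'   relative to the calibrator (which must be one of the names, at 0).
#' @param n_samples biological samples per group.
#' @param base_ct_target,base_ct_reference calibrator-group mean Ct values.
#' @param noise_sd per-measurement Ct noise standard deviation.
#' @param seed integer seed.
#' @return data.frame: sample, group, ct_target, ct_reference.
#' @export
simulate_qpcr <- function(group_log2_expr, n_samples = 4,
                          base_ct_target = 24, base_ct_reference = 18,
                          noise_sd = 0.2, seed = 1L) {
  stopifnot(!is.null(names(group_log2_expr)), noise_sd >= 0)
  set.seed(seed)
  rows <- lapply(names(group_log2_expr), function(g) {
    data.frame(
      sample = sprintf("%s_%d", g, seq_len(n_samples)),
      group = g,
      ct_target = base_ct_target - group_log2_expr[[g]] +
        rnorm(n_samples, 0, noise_sd),
      ct_reference = base_ct_reference + rnorm(n_samples, 0, noise_sd),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate grip-strength trials and fiber counts
#'
#' Grip trials (grams) are Gaussian around per-mouse pre/post means; central
#' nuclei counts are Binomial over the fibers scored per mouse.
#'
#' @param n_mice mice per group.
#' @param pre_mean,post_mean mean peak pull force (g) before/after treatment.
#' @param trial_sd trial-to-trial standard deviation (g).
#' @param body_weight_mean,body_weight_sd body weight distribution (g).
#' @param fibers_per_mouse fibers scored per mouse.
#' @param central_rate true probability a fiber shows a central nucleus.
#' @param seed integer seed.
#' @return list with `grip` (mouse, weight_g, pre1..3, post1..3) and
#'   `fibers` (mouse, total_fibers, central_count).
#' @export
simulate_assay_records <- function(n_mice = 5, pre_mean = 90, post_mean = 100,
                                   trial_sd = 8, body_weight_mean = 25,
                                   body_weight_sd = 2,
                                   fibers_per_mouse = 500, central_rate = 0.3,
                                   seed = 1L) {
  stopifnot(n_mice >= 1, fibers_per_mouse >= 1,
            central_rate >= 0, central_rate <= 1)
  set.seed(seed)
  grip <- data.frame(mouse = sprintf("m%02d", seq_len(n_mice)),
                     weight_g = rnorm(n_mice, body_weight_mean, body_weight_sd))
  for (k in 1:3) grip[[paste0("pre", k)]] <-
    pmax(0, rnorm(n_mice, pre_mean, trial_sd))
  for (k in 1:3) grip[[paste0("post", k)]] <-
    pmax(0, rnorm(n_mice, post_mean, trial_sd))
  fibers <- data.frame(mouse = grip$mouse,
                       total_fibers = rep(fibers_per_mouse, n_mice),
                       central_count = rbinom(n_mice, fibers_per_mouse,
                                              central_rate))
  list(grip = grip, fibers = fibers)
}

#' Four-parameter logistic on log10 dose
#'
#' @param log_dose log10 concentration.
#' @param bottom,top lower/upper asymptotes.
#' @param log_tc50 log10 of the midpoint concentration.
#' @param hill hill slope.
#' @return response at each `log_dose`.
#' @export
four_pl <- function(log_dose, bottom, top, log_tc50, hill) {
  bottom + (top - bottom) / (1 + 10^((log_tc50 - log_dose) * hill))
}
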