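#' Viability-plate percent inhibition
#'
#' Normalizes a transfected well's absorbance against the plate controls:
#' `100 - (abs_transfected - mean_media_only) * 100 / mean_untransfected`.
#' On this scale 0 is fully viable (signal equal to untreated cells) and 100
#' is a fully inhibited signal; the TC50 is the dose at which the fitted
#' curve crosses 50.
#'
#' @param abs_transfected absorbance of the treated well(s) (vectorized).
#' @param mean_media_only mean absorbance of media-only blanks.
#' @param mean_untransfected mean absorbance of untreated cell controls
#'   (must be positive).
#' @return percent inhibition.
#' @export
percent_inhibition <- function(abs_transfected, mean_media_only,
                               mean_untransfected) {
  if (mean_untransfected <= 0)
    stop("mean_untransfected must be positive")
  100 - (abs_transfected - mean_media_only) * 100 / mean_untransfected
}

#' Four-parameter logistic dose-response fit and TC50
#'
#' Least-squares 4PL fit on log10 dose via Levenberg-Marquardt
#' (`minpack.lm::nlsLM`). Because responses arrive percent-normalized (0 =
#' fully viable, 100 = fully inhibited signal), the default fits the
#' normalized-response model with asymptotes pinned at 0 and 100 — the
#' midpoint and hill slope are then well identified from a six-point dose
#' screen. Set `free_asymptotes = TRUE` for the fully free four-parameter
#' fit, initialized from the data (bottom = min response, top = max,
#' midpoint = median log dose, hill = 1) with up to three deterministic
#' restarts on failure. Degenerate inputs (flat responses) or
#' non-convergence yield a flagged result rather than an error.
#'
#' @param doses concentrations in nM (>= 4 distinct values).
#' @param responses normalized responses (same length as `doses`).
#' @param free_asymptotes fit bottom/top as free parameters.
#' @return list with `tc50` (nM), `fit` (named coefficients bottom, top,
#'   log_tc50, hill), `converged`, `degenerate`, and the `nls` object (or
#'   `NULL`).
#' @export
fit_tc50 <- function(doses, responses, free_asymptotes = FALSE) {
  stopifnot(length(doses) == length(responses), all(is.finite(responses)))
  if (any(doses <= 0)) stop("doses must be positive")
  if (length(unique(doses)) < 4)
    stop("need at least 4 distinct doses for a 4PL fit")
  if (diff(range(responses)) < 1e-8) {
    return(list(tc50 = NA_real_, fit = NULL, converged = FALSE,
                degenerate = TRUE, nls = NULL))
  }
  ld <- log10(doses)
  df <- data.frame(ld = ld, y = responses)
  start0 <- list(bottom = min(responses), top = max(responses),
                 log_tc50 = stats::median(ld), hill = 1)
  fit <- NULL
  for (attempt in 0:3) {
    start <- start0
    if (attempt > 0) {
      # fixed restart offsets, so refits never touch the caller's RNG state
      start$log_tc50 <- start0$log_tc50 + c(0, -1, 1, 0)[attempt + 1]
      start$hill <- start0$hill * c(1, 0.5, 2, 4)[attempt + 1]
    }
    fit <- tryCatch(
      if (free_asymptotes) {
        minpack.lm::nlsLM(
          y ~ four_pl(ld, bottom, top, log_tc50, hill),
          data = df, start = start,
          lower = c(bottom = -Inf, top = -Inf, log_tc50 = -Inf,
                    hill = 1e-3),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(
          y ~ four_pl(ld, 0, 100, log_tc50, hill),
          data = df, start = start[c("log_tc50", "hill")],
          lower = c(log_tc50 = -Inf, hill = 1e-3),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      },
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    return(list(tc50 = NA_real_, fit = NULL, converged = FALSE,
                degenerate = FALSE, nls = NULL))
  }
  co <- stats::coef(fit)
  if (!free_asymptotes) co <- c(bottom = 0, top = 100, co)
  if (co[["bottom"]] > co[["top"]]) {  # enforce bottom <= top orientation
    co[c("bottom", "top")] <- co[c("top", "bottom")]
  }
  list(tc50 = 10^co[["log_tc50"]],
       fit = co, converged = TRUE, degenerate = FALSE, nls = fit)
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct_target - Ct_reference`; per group, `ddCt` is the
#' group's mean dCt minus the calibrator group's mean dCt; relative quantity
#' is `2^-ddCt`, so the calibrator group is exactly 1. Technical replicates
#' should be averaged per sample before calling.
#'
#' @param records data.frame with columns `sample`, `group`, `ct_target`,
#'   `ct_reference`.
#' @param calibrator_group the group everything is calibrated against.
#' @return data.frame with one row per group: `group`, `mean_dct`, `ddct`,
#'   `rq`.
#' @export
relative_expression_ddct <- function(records, calibrator_group) {
  req <- c("sample", "group", "ct_target", "ct_reference")
  stopifnot(all(req %in% names(records)))
  if (anyNA(records$ct_reference) || anyNA(records$ct_target))
    stop("missing Ct values")
  if (!calibrator_group %in% records$group)
    stop(sprintf("calibrator group '%s' absent", calibrator_group))
  dct <- records$ct_target - records$ct_reference
  mean_dct <- tapply(dct, records$group, mean)
  ddct <- mean_dct - mean_dct[[calibrator_group]]
  data.frame(group = names(mean_dct),
             mean_dct = as.numeric(mean_dct),
             ddct = as.numeric(ddct),
             rq = 2^-as.numeric(ddct),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mean pixel intensity
#'
#' Image-quantification readout: the summed gray value of supra-threshold
#' pixels divided by the measured area. Thresholding (pixels below the cutoff
#' excluded from the sum) happens upstream; this applies the printed ratio.
#'
#' @param gray_value_sum summed gray value of pixels above threshold.
#' @param area cell/region area (must be positive).
#' @param threshold the gray-value cutoff used upstream (recorded only).
#' @return intensity per unit area.
#' @export
mean_pixel_intensity <- function(gray_value_sum, area, threshold = 10) {
  if (any(area <= 0)) stop("area must be positive")
  gray_value_sum / area
}

#' Grip-strength percent of normal force
#'
#' Normalizes the average post-treatment peak pull force to the
#' pre-treatment average and divides by body weight:
#' `100 * (mean post / mean pre) / weight`.
#'
#' @param pre,post numeric trial forces in grams (typically 3 each).
#' @param weight_g body weight in grams.
#' @return percent of normal force per gram body weight.
#' @export
percent_normal_force <- function(pre, post, weight_g) {
  if (mean(pre) <= 0) stop("mean pre-treatment force must be positive")
  if (weight_g <= 0) stop("body weight must be positive")
  100 * (mean(post) / mean(pre)) / weight_g
}

#' Central-nuclei percentage
#'
#' Histology readout: the percentage of scored muscle fibers whose nuclei sit
#' centrally.
#'
#' @param central_count fibers with central nuclei.
#' @param total_fibers fibers scored (> 0).
#' @return percentage (vectorized).
#' @export
central_nuclei_percent <- function(central_count, total_fibers) {
  if (any(total_fibers <= 0)) stop("total_fibers must be positive")
  if (any(central_count < 0) || any(central_count > total_fibers))
    stop("central_count must lie in [0, total_fibers]")
  100 * central_count / total_fibers
}
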