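#' ROI mean and noise measurements
#'
#' Image noise is defined as the standard deviation of the HU values inside
#' a fixed-area (nominally 50 mm^2) ROI; the sample (n-1) standard
#' deviation is used. One row is returned per ROI.
#'
#' @param image a `recon_image` (or [phantom_image()]).
#' @param rois tibble of ROI specs (`tissue`, `roi_id`, `cx_mm`, `cy_mm`,
#'   `area_mm2`), as produced by [default_swine_phantom()].
#' @return tibble with columns `tissue`, `roi_id`, `dose_mas`,
#'   `provenance`, `n_px`, `mean_hu`, `sd_hu`.
#' @export
roi_stats <- function(image, rois) {
  rois <- as.data.frame(rois)
  if (!nrow(rois)) rlang::abort("no ROIs supplied")
  purrr::map_dfr(seq_len(nrow(rois)), function(i) {
    m <- roi_mask(rois[i, ], image)
    vals <- image$hu[m]
    if (!length(vals)) rlang::abort("ROI mask is empty")
    tibble::tibble(
      tissue = as.character(rois$tissue[i]),
      roi_id = rois$roi_id[i] %||% i,
      dose_mas = image$source_mas %||% NA_real_,
      provenance = image$provenance %||% "original",
      n_px = length(vals),
      mean_hu = mean(vals),
      sd_hu = if (length(vals) > 1) stats::sd(vals) else 0
    )
  })
}

#' Percent discrepancy between simulated and original values
#'
#' `100 * (sim - orig) / orig`. The sign convention is asymmetric by
#' construction: a negative value means the simulation under-reads the
#' original.
#'
#' @param sim,orig numeric vectors (HU or noise values); `orig` must be
#'   nonzero.
#' @return percent discrepancies, same length as the inputs.
#' @export
percent_discrepancy <- function(sim, orig) {
  if (any(orig == 0)) {
    rlang::abort("relative discrepancy undefined for orig = 0")
  }
  100 * (sim - orig) / orig
}

#' Paired mean difference with Student-t confidence interval
#'
#' @param orig,sim paired numeric vectors, n >= 2.
#' @param level confidence level (default 0.95).
#' @return tibble with `mean_diff`, `ci_low`, `ci_high`, `n`.
#' @export
mean_difference_ci <- function(orig, sim, level = 0.95) {
  if (length(orig) != length(sim)) rlang::abort("orig/sim lengths differ")
  if (length(orig) < 2) rlang::abort("need at least 2 pairs")
  d <- sim - orig
  if (stats::sd(d) == 0) {
    return(tibble::tibble(mean_diff = mean(d), ci_low = mean(d),
                          ci_high = mean(d), n = length(d)))
  }
  tt <- stats::t.test(d, conf.level = level)
  tibble::tibble(mean_diff = mean(d), ci_low = tt$conf.int[1],
                 ci_high = tt$conf.int[2], n = length(d))
}

#' Two-tailed paired Student t-test
#'
#' @param x,y paired numeric vectors of equal length, n >= 2.
#' @return tibble with `t`, `df`, `p`; for zero-variance differences
#'   (x identical to y) returns `t = 0`, `p = 1`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) rlang::abort("x and y must have equal length")
  if (length(x) < 2) rlang::abort("need at least 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    return(tibble::tibble(t = 0, df = length(d) - 1, p = 1))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
}

#' Observer-study summary counts
#'
#' Sums per-observer 2x2 confusion tables (true original/simulated vs
#' rated original/simulated). Column convention: `oo` originals rated
#' original, `os` originals rated simulated, `so` simulations rated
#' original, `ss` simulations rated simulated.
#'
#' @param tables tibble with columns `observer`, `oo`, `os`, `so`, `ss`;
#'   one row per observer.
#' @return one-row tibble: `n_total`, `n_correct`, `n_incorrect`,
#'   `n_orig_correct`, `n_sim_correct`, `n_sim_rated_orig`,
#'   `n_orig_rated_sim` and the corresponding proportions (`p_*`).
#' @export
observer_summary <- function(tables) {
  tables <- as.data.frame(tables)
  if (!nrow(tables)) rlang::abort("need at least one observer table")
  cols <- c("oo", "os", "so", "ss")
  if (!all(cols %in% names(tables))) {
    rlang::abort("tables needs columns oo, os, so, ss")
  }
  if (any(as.matrix(tables[cols]) < 0)) rlang::abort("negative counts")
  s <- colSums(tables[cols])
  n_total <- sum(s)
  tibble::tibble(
    n_total = n_total,
    n_correct = s[["oo"]] + s[["ss"]],
    n_incorrect = s[["os"]] + s[["so"]],
    n_orig_correct = s[["oo"]],
    n_sim_correct = s[["ss"]],
    n_sim_rated_orig = s[["so"]],
    n_orig_rated_sim = s[["os"]],
    p_correct = (s[["oo"]] + s[["ss"]]) / n_total,
    p_orig_correct = s[["oo"]] / n_total,
    p_sim_correct = s[["ss"]] / n_total
  )
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with the
#' expected agreement `p_e` from the product of the raters' marginal
#' proportions. When both raters agree perfectly and `p_e = 1` (a single
#' category used throughout), kappa is defined as 1.
#'
#' @param ratings_a,ratings_b equal-length vectors of category labels
#'   (e.g. 1 = rated original, 2 = rated simulated).
#' @return kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b)) {
    rlang::abort("rating vectors must have equal length")
  }
  if (!length(ratings_a)) rlang::abort("need at least one rating")
  n <- length(ratings_a)
  levs <- union(unique(ratings_a), unique(ratings_b))
  tab <- table(factor(ratings_a, levels = levs),
               factor(ratings_b, levels = levs))
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (p_e == 1) return(if (p_o == 1) 1 else 0)
  (p_o - p_e) / (1 - p_e)
}

#' Exact binomial test against chance-level discrimination
#'
#' Two-sided exact binomial test of `n_correct` successes in `n_total`
#' Bernoulli(0.5) trials — did observers discriminate original from
#' simulated images above chance?
#'
#' @param n_correct,n_total counts, `0 <= n_correct <= n_total`.
#' @return two-sided p-value.
#' @export
chance_level_test <- function(n_correct, n_total) {
  stopifnot(n_correct >= 0, n_correct <= n_total)
  stats::binom.test(n_correct, n_total, p = 0.5)$p.value
}

#' Scale a CTDI dose index to another tube load
#'
#' CTDI is linear in mAs at fixed tube voltage:
#' `ctdi_ref * mas_target / mas_ref`.
#'
#' @param ctdi_ref reference CTDI (mGy) measured at `mas_ref`.
#' @param mas_ref,mas_target tube loads (mAs), all positive.
#' @return CTDI at `mas_target` in mGy.
#' @export
ctdi_scale <- function(ctdi_ref, mas_ref, mas_target) {
  if (any(c(ctdi_ref, mas_ref, mas_target) <= 0)) {
    rlang::abort("all inputs must be positive")
  }
  ctdi_ref * mas_target / mas_ref
}
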