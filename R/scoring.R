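#' Topographic profile rating: raw pattern expression of one scan
#'
#' Forward single-scan scoring against a fixed pattern: the scan is globally
#' normalized over the pattern's mask, log-transformed, centered by its own
#' masked mean (the single-subject counterpart of row centering), the stored
#' group mean profile is subtracted, and the raw score is the inner product
#' of the residual with the pattern weights. Applied to a derivation scan
#' this reproduces its derivation score exactly, because the centering and
#' GMP bookkeeping are identical.
#'
#' @param pattern A `covariance_pattern` (from [derive_pattern()] or
#'   [load_pattern()]).
#' @param scan A [pet_scan()], preprocessed the same way as the derivation
#'   scans (same smoothing); grid and mask must match the pattern's
#'   fingerprint — a mismatch errors rather than silently resampling.
#' @param smooth_fwhm_mm Optional FWHM to apply before scoring (use the
#'   derivation value for raw scans; `0` if the scan is already smoothed).
#' @return Raw expression score (numeric scalar).
#' @export
tpr_score <- function(pattern, scan, smooth_fwhm_mm = 0) {
  if (!inherits(pattern, "covariance_pattern"))
    stop("`pattern` must be a covariance_pattern")
  if (smooth_fwhm_mm > 0) scan <- smooth_gaussian(scan, smooth_fwhm_mm)
  check_same_grid(scan, pattern$mask)
  if (!identical(mask_fingerprint(pattern$mask), pattern$fingerprint))
    stop("mask fingerprint mismatch: scan ordering differs from derivation")
  l <- log_transform(normalize_global(scan, pattern$mask), pattern$mask)
  resid <- (l - mean(l)) - pattern$gmp
  sum(pattern$weights * resid)
}

#' Z-transform raw expression scores
#'
#' Affine, order-preserving map `(raw - mean) / sd` using the pattern's
#' stored reference (control mean and control or pooled SD).
#'
#' @param raw_scores Numeric vector of raw scores.
#' @param z_ref List with `mean` and `sd` (`sd > 0`), e.g. `pattern$z_ref`.
#' @return Numeric vector of Z scores.
#' @export
zscore <- function(raw_scores, z_ref) {
  if (!is.finite(z_ref$sd) || z_ref$sd <= 0) stop("z_ref$sd must be positive")
  (raw_scores - z_ref$mean) / z_ref$sd
}

#' Score a set of scans against a pattern
#'
#' @inheritParams tpr_score
#' @param scans List of [pet_scan()]s.
#' @param timepoint Label stored with the scores (e.g. `"baseline"`,
#'   `"post"`).
#' @return data.frame with columns `id`, `timepoint`, `raw`, `z`.
#' @export
score_scans <- function(pattern, scans, timepoint = "baseline",
                        smooth_fwhm_mm = 0) {
  raw <- vapply(scans, function(s) tpr_score(pattern, s, smooth_fwhm_mm),
                numeric(1))
  data.frame(id = vapply(scans, function(s) s$id, character(1)),
             timepoint = timepoint, raw = raw,
             z = zscore(raw, pattern$z_ref), stringsAsFactors = FALSE)
}

#' Treatment-induced decline in pattern expression
#'
#' Pairs baseline and post-treatment Z scores by subject id and returns
#' `baseline z - post z`, so a positive decline means expression decreased
#' after treatment. Both timepoints are scored against the same fixed
#' baseline-derived pattern and its baseline Z reference.
#'
#' @param baseline,post data.frames with columns `id` and `z` (as returned
#'   by [score_scans()]); ids must pair one-to-one.
#' @return data.frame with columns `id`, `baseline_z`, `post_z`, `decline`.
#' @export
score_change <- function(baseline, post) {
  if (!all(c("id", "z") %in% names(baseline)) ||
      !all(c("id", "z") %in% names(post)))
    stop("need data.frames with `id` and `z` columns")
  if (anyDuplicated(baseline$id) || anyDuplicated(post$id))
    stop("duplicate subject ids")
  if (!setequal(baseline$id, post$id))
    stop("unpaired subject ids between timepoints")
  m <- match(baseline$id, post$id)
  data.frame(id = baseline$id, baseline_z = baseline$z, post_z = post$z[m],
             decline = baseline$z - post$z[m], stringsAsFactors = FALSE)
}
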