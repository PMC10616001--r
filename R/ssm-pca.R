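#' Assemble the subject-by-voxel log-intensity matrix
#'
#' Each row is a subject's globally normalized, log-transformed masked scan
#' ([normalize_global()] then [log_transform()]), in the fixed voxel ordering
#' recorded by the mask fingerprint.
#'
#' @param scans List of preprocessed [pet_scan()]s on one grid.
#' @param mask The common analysis [pet_mask()].
#' @param labels Factor or character vector, `"control"`/`"patient"`, one per
#'   scan; at least 3 subjects per group.
#' @return A `subject_matrix`: `x` (subjects x voxels), `labels`, `ids`,
#'   `mask`, `fingerprint`.
#' @export
build_matrix <- function(scans, mask, labels) {
  if (length(scans) != length(labels)) stop("one label per scan required")
  labels <- factor(as.character(labels), levels = c("control", "patient"))
  if (anyNA(labels)) stop("labels must be 'control' or 'patient'")
  if (any(table(labels) < 3L)) stop("need at least 3 subjects per group")
  x <- t(vapply(scans,
                function(s) log_transform(normalize_global(s, mask), mask),
                numeric(mask$n_voxels)))
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite log intensities")
  rownames(x) <- vapply(scans, function(s) s$id, character(1))
  structure(
    list(x = x, labels = labels, ids = rownames(x), mask = mask,
         fingerprint = mask_fingerprint(mask)),
    class = "subject_matrix"
  )
}

#' Double-center the subject matrix (SSM residual profiles)
#'
#' Subtracts each subject's row mean — removing the additive log-domain
#' global offset, i.e. multiplicative scanner/dose scaling — and then each
#' voxel's column mean across subjects. The stored column-mean profile is the
#' group mean profile (GMP) that prospective scoring must subtract; the
#' doubly centered rows are the subject residual profiles (SRP).
#'
#' @param sm A [build_matrix()] result.
#' @return A `residual_profiles`: `srp` (subjects x voxels, row and column
#'   means zero), `gmp` (length-voxels reference profile), plus the labels,
#'   ids, mask and fingerprint carried through.
#' @export
double_center <- function(sm) {
  if (!inherits(sm, "subject_matrix")) stop("`sm` must be a subject_matrix")
  r <- sm$x - rowMeans(sm$x)
  gmp <- colMeans(r)
  srp <- sweep(r, 2L, gmp)
  structure(
    list(srp = srp, gmp = gmp, labels = sm$labels, ids = sm$ids,
         mask = sm$mask, fingerprint = sm$fingerprint),
    class = "residual_profiles"
  )
}

# Deterministic eigenvector sign convention: the largest-magnitude loading
# coefficient of each component is made positive (first index on ties).
fix_signs <- function(loadings, scores) {
  for (k in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, k]))
    if (loadings[i, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  list(loadings = loadings, scores = scores)
}

#' Principal components of the subject residual profiles
#'
#' Eigen-decomposition of the voxel-space covariance of the SRP, computed via
#' the thin SVD (numerically equivalent to, and much cheaper than, forming
#' the voxel-by-voxel covariance; the subject-space route `S S^T` gives the
#' same result up to sign, which the deterministic sign rule removes).
#' Components are ordered by decreasing variance accounted for.
#'
#' @param res A [double_center()] result.
#' @return A `component_set`: `loadings` (voxels x k, orthonormal columns),
#'   `subject_scores` (subjects x k, equal to `srp %*% loadings`), `vaf`
#'   (variance fractions summing to 1 over the retained rank).
#' @export
principal_components <- function(res) {
  if (!inherits(res, "residual_profiles"))
    stop("`res` must come from double_center()")
  sv <- svd(res$srp)
  tol <- max(dim(res$srp)) * max(sv$d) * .Machine$double.eps
  keep <- sv$d > max(tol, 0)
  if (!any(keep)) stop("no variance: residual profiles are all zero")
  d <- sv$d[keep]
  fx <- fix_signs(sv$v[, keep, drop = FALSE],
                  sv$u[, keep, drop = FALSE] %*% diag(d, length(d)))
  structure(
    list(loadings = fx$loadings, subject_scores = fx$scores,
         vaf = d^2 / sum(d^2), labels = res$labels, ids = res$ids,
         gmp = res$gmp, mask = res$mask, fingerprint = res$fingerprint),
    class = "component_set"
  )
}

#' Derive the disease-related covariance pattern
#'
#' Selects the smallest prefix of components whose cumulative variance
#' accounted for reaches `vaf_cutoff`, then combines them by the Fisher
#' linear discriminant of the group labels in component-score space (pooled
#' within-group covariance with a small ridge), maximizing the separation of
#' patient and control expression. The resulting voxel-weight topography is
#' unit-norm, with the sign fixed so patients express the pattern more than
#' controls. Expression is Z-scored against the control reference
#' (`z_convention = "control"`: control scores have mean 0 and SD 1 by
#' construction) or against the combined-sample SD (`"pooled"`: control mean
#' still maps to 0).
#'
#' @param comp A [principal_components()] result.
#' @param vaf_cutoff Cumulative variance fraction for the candidate prefix
#'   (default 0.5).
#' @param z_convention `"control"` or `"pooled"` (see above).
#' @param ridge Ridge added to the pooled within-group covariance diagonal.
#' @return A list with `pattern` (a `covariance_pattern`) and `scores`
#'   (data.frame: id, label, raw, z).
#' @export
derive_pattern <- function(comp, vaf_cutoff = 0.5,
                           z_convention = c("control", "pooled"),
                           ridge = 1e-8) {
  if (!inherits(comp, "component_set"))
    stop("`comp` must come from principal_components()")
  z_convention <- match.arg(z_convention)
  if (vaf_cutoff <= 0 || vaf_cutoff > 1) stop("`vaf_cutoff` must be in (0, 1]")
  labels <- comp$labels
  if (nlevels(droplevels(labels)) < 2L) stop("both groups must be present")

  k <- which(cumsum(comp$vaf) >= vaf_cutoff - 1e-12)[1]
  idx <- seq_len(k)
  sc <- comp$subject_scores[, idx, drop = FALSE]
  ctrl <- labels == "control"

  mu_c <- colMeans(sc[ctrl, , drop = FALSE])
  mu_p <- colMeans(sc[!ctrl, , drop = FALSE])
  cw <- (crossprod(scale(sc[ctrl, , drop = FALSE], center = TRUE, scale = FALSE)) +
         crossprod(scale(sc[!ctrl, , drop = FALSE], center = TRUE, scale = FALSE))) /
        (nrow(sc) - 2)
  cw <- cw + diag(ridge, k)
  coef <- tryCatch(solve(cw, mu_p - mu_c),
                   error = function(e) stop("singular within-group covariance"))
  coef <- coef / sqrt(sum(coef^2))

  w <- as.numeric(comp$loadings[, idx, drop = FALSE] %*% coef)
  raw <- as.numeric(sc %*% coef)  # = srp %*% w since loadings are orthonormal
  if (mean(raw[!ctrl]) < mean(raw[ctrl])) {
    w <- -w; raw <- -raw; coef <- -coef
  }

  z_mean <- mean(raw[ctrl])
  z_sd <- if (z_convention == "control") stats::sd(raw[ctrl]) else stats::sd(raw)
  if (!is.finite(z_sd) || z_sd <= 0) stop("degenerate score spread")
  z_ref <- list(mean = z_mean, sd = z_sd, convention = z_convention)

  pattern <- structure(
    list(weights = w, gmp = comp$gmp, mask = comp$mask,
         fingerprint = comp$fingerprint, component_indices = idx,
         coefficients = as.numeric(coef), vaf = comp$vaf[idx], z_ref = z_ref,
         provenance = list(n_control = sum(ctrl), n_patient = sum(!ctrl))),
    class = "covariance_pattern"
  )
  scores <- data.frame(id = comp$ids, label = as.character(labels),
                       raw = raw, z = (raw - z_mean) / z_sd,
                       stringsAsFactors = FALSE)
  list(pattern = pattern, scores = scores)
}

#' @export
print.covariance_pattern <- function(x, ...) {
  cat(sprintf(paste0("<covariance_pattern> %d voxels, components %s ",
                     "(VAF %s), z_ref %.4g +/- %.4g [%s]\n"),
              length(x$weights),
              paste(x$component_indices, collapse = ","),
              paste(sprintf("%.2f", x$vaf), collapse = ","),
              x$z_ref$mean, x$z_ref$sd, x$z_ref$convention))
  invisible(x)
}

#' Derive a covariance pattern from raw scans (one call)
#'
#' Convenience wrapper: smooth, derive (or accept) the analysis mask, build
#' the subject matrix, double-center, extract principal components, and
#' combine them into the discriminant pattern.
#'
#' @param scans List of co-registered [pet_scan()]s.
#' @param labels `"control"`/`"patient"` per scan.
#' @param mask Optional [pet_mask()]; derived from the smoothed scans via
#'   [compute_mask()] when `NULL`.
#' @param fwhm_mm Smoothing kernel FWHM in mm (0 disables smoothing).
#' @param mask_fraction Threshold for [compute_mask()].
#' @inheritParams derive_pattern
#' @return As [derive_pattern()], plus `mask` and the `component_set`.
#' @export
derive_covariance_pattern <- function(scans, labels, mask = NULL,
                                      fwhm_mm = 10, mask_fraction = 0.2,
                                      vaf_cutoff = 0.5,
                                      z_convention = c("control", "pooled"),
                                      ridge = 1e-8) {
  z_convention <- match.arg(z_convention)
  if (fwhm_mm > 0) scans <- lapply(scans, smooth_gaussian, fwhm_mm = fwhm_mm)
  if (is.null(mask)) mask <- compute_mask(scans, mask_fraction)
  comp <- principal_components(double_center(build_matrix(scans, mask, labels)))
  out <- derive_pattern(comp, vaf_cutoff = vaf_cutoff,
                        z_convention = z_convention, ridge = ridge)
  out$mask <- mask
  out$components <- comp
  out
}

#' Save a derived pattern as a NIfTI weight map + JSON sidecar
#'
#' The weight map has the pattern weights at masked voxels and 0 elsewhere;
#' the JSON records the GMP, Z reference, component bookkeeping and the mask
#' fingerprint needed for prospective scoring.
#'
#' @param pattern A `covariance_pattern`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_pattern <- function(pattern, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vol <- array(0, dim(pattern$mask$indicator))
  vol[mask_indices(pattern$mask)] <- pattern$weights
  write_scan(vol, file.path(dir, "pattern_weights.nii.gz"),
             spacing_mm = pattern$mask$spacing_mm)
  write_scan(pattern$mask, file.path(dir, "pattern_mask.nii.gz"))
  meta <- list(gmp = pattern$gmp, fingerprint = pattern$fingerprint,
               component_indices = pattern$component_indices,
               coefficients = pattern$coefficients, vaf = pattern$vaf,
               z_ref = pattern$z_ref, provenance = pattern$provenance,
               voxel_ordering = "column-major over the mask")
  jsonlite::write_json(meta, file.path(dir, "pattern.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a pattern saved by [save_pattern()]
#'
#' @param dir Directory holding `pattern_weights.nii.gz`,
#'   `pattern_mask.nii.gz` and `pattern.json`.
#' @return A `covariance_pattern`.
#' @export
load_pattern <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "pattern.json"),
                              simplifyVector = TRUE)
  mvol <- read_scan(file.path(dir, "pattern_mask.nii.gz"))
  mask <- pet_mask(mvol$values > 0.5, mvol$spacing_mm)
  # weight maps are signed, so bypass the non-negative pet_scan contract
  wimg <- RNifti::readNifti(file.path(dir, "pattern_weights.nii.gz"))
  wvals <- array(as.numeric(wimg), dim = dim(wimg))
  structure(
    list(weights = wvals[mask_indices(mask)], gmp = meta$gmp,
         mask = mask, fingerprint = meta$fingerprint,
         component_indices = meta$component_indices,
         coefficients = meta$coefficients, vaf = meta$vaf,
         z_ref = as.list(meta$z_ref), provenance = as.list(meta$provenance)),
    class = "covariance_pattern"
  )
}
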