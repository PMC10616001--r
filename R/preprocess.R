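# 1D Gaussian convolution matrix with row renormalization: rows sum to one,
# so a constant signal passes through unchanged even at the boundary.
gauss_conv_matrix <- function(n, sigma_vox) {
  if (sigma_vox < 1e-8) return(diag(n))
  radius <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  offs <- -radius:radius
  k <- exp(-offs^2 / (2 * sigma_vox^2))
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + offs
    ok <- j >= 1 & j <= n
    A[i, j[ok]] <- k[ok] / sum(k[ok])
  }
  A
}

#' Smooth a scan with a separable 3D Gaussian kernel
#'
#' The kernel is specified by its full width at half maximum in mm and
#' converted per axis to voxel units via the scan spacing
#' (`sigma = FWHM / (2 sqrt(2 ln 2)) / spacing`), so anisotropic spacing is
#' handled naturally. The truncated kernel (4 SD) is renormalized at the
#' volume boundary so a constant volume is preserved exactly.
#'
#' @param scan A [pet_scan()].
#' @param fwhm_mm Positive kernel FWHM in mm (the study protocol uses 10 mm).
#' @return The smoothed [pet_scan()].
#' @export
smooth_gaussian <- function(scan, fwhm_mm = 10) {
  if (!inherits(scan, "pet_scan")) stop("`scan` must be a pet_scan")
  if (!is.finite(fwhm_mm) || fwhm_mm <= 0) stop("`fwhm_mm` must be positive")
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  dm <- dim(scan$values)
  v <- scan$values
  for (a in 1:3) {
    A <- gauss_conv_matrix(dm[a], sigma_mm / scan$spacing_mm[a])
    perm <- c(a, setdiff(1:3, a))
    v <- aperm(v, perm)
    v <- array(A %*% matrix(v, nrow = dm[a]), dim = dm[perm])
    v <- aperm(v, order(perm))
  }
  pet_scan(pmax(v, 0), scan$spacing_mm, id = scan$id, units = scan$units)
}

#' Derive a common analysis mask from a set of scans
#'
#' A voxel enters the mask iff, in every scan, its value exceeds `fraction`
#' times that scan's mean over its positive voxels. The intersection across
#' scans guarantees a common support for the subject-by-voxel matrix. A
#' user-supplied anatomical mask can be used instead wherever a `pet_mask`
#' is accepted.
#'
#' @param scans List of [pet_scan()]s on one grid.
#' @param fraction Threshold fraction in (0, 1); default 0.2.
#' @return A [pet_mask()].
#' @export
compute_mask <- function(scans, fraction = 0.2) {
  if (inherits(scans, "pet_scan")) scans <- list(scans)
  if (length(scans) < 1L) stop("need at least one scan")
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must be in (0, 1)")
  dm <- dim(scans[[1]]$values)
  keep <- array(TRUE, dm)
  for (s in scans) {
    if (!identical(dim(s$values), dm)) stop("scan grids differ")
    pos <- s$values[s$values > 0]
    if (length(pos) == 0L) stop("empty mask: a scan has no positive voxels")
    keep <- keep & (s$values > fraction * mean(pos))
  }
  if (!any(keep)) stop("empty mask")
  pet_mask(keep, scans[[1]]$spacing_mm)
}

#' Normalize a scan by its whole-brain (masked) mean
#'
#' Voxel-wise intensity normalization with the whole brain as the reference
#' region: values are divided by the scan's mean over the mask, so the masked
#' mean becomes exactly 1 and the result is invariant to global rescaling of
#' the input.
#'
#' @param scan A [pet_scan()].
#' @param mask A [pet_mask()] on the same grid.
#' @return The normalized [pet_scan()].
#' @export
normalize_global <- function(scan, mask) {
  check_same_grid(scan, mask)
  m <- mean(scan$values[mask$indicator])
  if (!is.finite(m) || m <= 0) stop("nonpositive masked mean")
  pet_scan(scan$values / m, scan$spacing_mm, id = scan$id, units = scan$units)
}

#' Masked log-intensity vector of a scan
#'
#' Natural log of `max(value, floor)` at masked voxels, in the package's
#' fixed column-major voxel ordering (the same ordering the derived pattern
#' records, so prospective scoring is bit-consistent with derivation).
#' Zeros or underflows inside the mask are floored, with a warning reporting
#' the count, rather than erroring: smoothed phantom edges may legitimately
#' underflow.
#'
#' @param scan A [pet_scan()] (typically already normalized).
#' @param mask A [pet_mask()].
#' @param floor Positive flooring value; default `1e-6` of the masked mean.
#' @return Numeric vector of length `mask$n_voxels`.
#' @export
log_transform <- function(scan, mask, floor = NULL) {
  check_same_grid(scan, mask)
  v <- scan$values[mask_indices(mask)]
  if (is.null(floor)) floor <- 1e-6 * mean(v)
  if (!is.finite(floor) || floor <= 0) stop("`floor` must be positive")
  n_floored <- sum(v < floor)
  if (n_floored > 0)
    warning(sprintf("%d masked voxel(s) at or below the floor were clamped",
                    n_floored))
  log(pmax(v, floor))
}
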