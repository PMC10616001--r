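#' PET scan container
#'
#' A `pet_scan` bundles a 3D voxel volume with its voxel spacing and intensity
#' semantics. Volumes are assumed already co-registered to a common space;
#' spatial normalization is outside the scope of this package.
#'
#' @param values Numeric 3D array of non-negative, finite intensities.
#' @param spacing_mm Positive numeric length-3 voxel spacing in mm.
#' @param id Scan identifier string.
#' @param units Intensity semantics: `"arbitrary"` (e.g. counts, to be
#'   intensity-normalized) or `"SUV"` (standardized uptake value).
#' @return An object of class `pet_scan` with fields `values`, `spacing_mm`,
#'   `id`, `units`.
#' @export
pet_scan <- function(values, spacing_mm, id = "scan",
                     units = c("arbitrary", "SUV")) {
  units <- match.arg(units)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (anyNA(values) || any(!is.finite(values)))
    stop("scan values must be finite")
  if (any(values < 0))
    stop("scan values must be non-negative")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("`spacing_mm` must be three positive numbers")
  structure(
    list(values = values, spacing_mm = spacing_mm,
         id = as.character(id), units = units),
    class = "pet_scan"
  )
}

#' @export
print.pet_scan <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<pet_scan '%s'> %dx%dx%d voxels @ %.3gx%.3gx%.3g mm [%s]\n",
              x$id, d[1], d[2], d[3],
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3], x$units))
  invisible(x)
}

#' Binary voxel mask
#'
#' @param indicator Logical 3D array marking included voxels.
#' @param spacing_mm Voxel spacing in mm (used for the voxel volume in mL).
#' @return A `pet_mask` with fields `indicator`, `spacing_mm`, `n_voxels`,
#'   `voxel_volume_ml`.
#' @export
pet_mask <- function(indicator, spacing_mm) {
  if (!is.array(indicator) || length(dim(indicator)) != 3L ||
      !is.logical(indicator))
    stop("`indicator` must be a logical 3D array")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be three positive numbers")
  n <- sum(indicator)
  if (n < 1L) stop("empty mask")
  structure(
    list(indicator = indicator, spacing_mm = spacing_mm,
         n_voxels = as.integer(n),
         voxel_volume_ml = prod(spacing_mm) / 1000),
    class = "pet_mask"
  )
}

#' @export
print.pet_mask <- function(x, ...) {
  cat(sprintf("<pet_mask> %d voxels (%.1f mL) in a %s grid\n",
              x$n_voxels, x$n_voxels * x$voxel_volume_ml,
              paste(dim(x$indicator), collapse = "x")))
  invisible(x)
}

# Linear voxel indices of the mask, in the package's fixed column-major
# ordering. All vectorized voxel data (log profiles, pattern weights) use
# this ordering; prospective scoring checks it via the mask fingerprint.
mask_indices <- function(mask) which(mask$indicator)

# Compact fingerprint of grid shape + mask support, used to refuse scoring
# a scan against a pattern derived on a different mask/ordering.
mask_fingerprint <- function(mask) {
  idx <- as.double(mask_indices(mask))
  paste(c(dim(mask$indicator), length(idx), sum(idx), sum(idx^2) %% 2^31),
        collapse = "-")
}

check_same_grid <- function(scan, mask) {
  if (!identical(dim(scan$values), dim(mask$indicator)))
    stop("scan and mask grids differ")
  if (max(abs(scan$spacing_mm - mask$spacing_mm)) > 1e-6)
    stop("scan and mask spacings differ")
  invisible(TRUE)
}

#' Read a NIfTI volume as a `pet_scan`
#'
#' @param path Path to a NIfTI-1 file (`.nii` or `.nii.gz`).
#' @inheritParams pet_scan
#' @return A [pet_scan()] with spacing taken from the header `pixdim`.
#' @export
read_scan <- function(path, id = NULL, units = c("arbitrary", "SUV")) {
  units <- match.arg(units)
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  if (length(dim(vals)) == 4L && dim(vals)[4] == 1L)
    vals <- array(vals, dim = dim(vals)[1:3])
  sp <- RNifti::pixdim(img)[1:3]
  if (is.null(id)) id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  pet_scan(vals, sp, id = id, units = units)
}

#' Write a `pet_scan` (or mask, or plain array) as NIfTI-1
#'
#' @param x A [pet_scan()], [pet_mask()], or numeric 3D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing_mm Spacing override; required when `x` is a bare array.
#' @return `path`, invisibly.
#' @export
write_scan <- function(x, path, spacing_mm = NULL) {
  if (inherits(x, "pet_scan")) {
    vals <- x$values; sp <- x$spacing_mm
  } else if (inherits(x, "pet_mask")) {
    vals <- x$indicator * 1; sp <- x$spacing_mm
  } else {
    vals <- x
    if (is.null(spacing_mm)) stop("`spacing_mm` required for a bare array")
    sp <- spacing_mm
  }
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}
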