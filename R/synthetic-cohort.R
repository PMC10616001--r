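#' Deterministic brain phantom template
#'
#' Builds an ellipsoidal "brain" occupying ~84% of each grid half-extent, with
#' a mean log-intensity field `mu` that is higher in an interior cortical
#' ("gray") shell than in the deep ("white") core — enough radial structure
#' that intensity normalization and double-centering have non-trivial work to
#' do. Fully deterministic.
#'
#' @param grid_shape Integer length-3 grid size in voxels (each >= 16).
#' @param spacing_mm Positive length-3 voxel spacing in mm.
#' @return A `phantom_template`: list with `grid_shape`, `spacing_mm`, `mu`
#'   (3D array of mean log intensity, `NA` outside the brain), and
#'   `brain_mask` (a [pet_mask()]).
#' @export
make_template <- function(grid_shape = c(64, 64, 48), spacing_mm = c(2, 2, 2)) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    stop("grid too small: need at least 16 voxels per axis")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing must be positive")

  ext <- grid_shape * spacing_mm
  ctr <- ext / 2
  semi <- 0.42 * ext  # ellipsoid semi-axes in mm
  ax <- lapply(1:3, function(a) {
    (seq_len(grid_shape[a]) - 0.5) * spacing_mm[a]
  })
  # normalized ellipsoidal radius at each voxel center
  r2 <- outer(outer(((ax[[1]] - ctr[1]) / semi[1])^2,
                    ((ax[[2]] - ctr[2]) / semi[2])^2, `+`),
              ((ax[[3]] - ctr[3]) / semi[3])^2, `+`)
  r <- sqrt(r2)
  mask <- pet_mask(r <= 1, spacing_mm)

  # white-matter-like core at exp(mu)=4, gray shell peaking near r=0.7 at ~6
  mu <- log(4 + 2 * exp(-((r - 0.7) / 0.18)^2))
  mu[!mask$indicator] <- NA_real_

  structure(
    list(grid_shape = grid_shape, spacing_mm = spacing_mm,
         mu = mu, brain_mask = mask),
    class = "phantom_template"
  )
}

#' A blob of a planted pattern
#'
#' @param center_mm Blob center in mm (voxel centers sit at
#'   `(index - 0.5) * spacing`).
#' @param radius_mm Gaussian standard deviation in mm; the blob is truncated
#'   at 3 radii.
#' @param polarity `+1` (relatively increased metabolism) or `-1` (decreased).
#' @param amplitude Non-negative blob height.
#' @export
pattern_blob <- function(center_mm, radius_mm, polarity = 1, amplitude = 1) {
  stopifnot(length(center_mm) == 3L, radius_mm > 0,
            polarity %in% c(-1, 1), amplitude >= 0)
  list(center_mm = as.numeric(center_mm), radius_mm = as.numeric(radius_mm),
       polarity = as.numeric(polarity), amplitude = as.numeric(amplitude))
}

#' Default planted-pattern specification
#'
#' Emulates the topography of a lymphoma-related metabolic brain pattern:
#' relative hypermetabolism in inferior/central structures (bilateral
#' cerebellum-like blobs and a brainstem/thalamus-like midline blob) and
#' relative hypometabolism in posterior-superior cortex (bilateral
#' parieto-occipital-like blobs). Coordinates are fractions of the grid
#' extent, so the spec scales with the template.
#'
#' @param template A [make_template()] result.
#' @return List of [pattern_blob()]s.
#' @export
default_pattern_spec <- function(template) {
  ext <- template$grid_shape * template$spacing_mm
  at <- function(fx, fy, fz) c(fx, fy, fz) * ext
  rad <- 0.09 * mean(ext)
  list(
    pattern_blob(at(0.38, 0.32, 0.30), rad, +1, 1),   # left cerebellum-like
    pattern_blob(at(0.62, 0.32, 0.30), rad, +1, 1),   # right cerebellum-like
    pattern_blob(at(0.50, 0.46, 0.42), rad, +1, 0.8), # brainstem/thalamus-like
    pattern_blob(at(0.40, 0.30, 0.62), rad, -1, 1),   # left occipito-parietal
    pattern_blob(at(0.60, 0.30, 0.62), rad, -1, 1),   # right occipito-parietal
    pattern_blob(at(0.50, 0.62, 0.68), rad, -1, 0.7)  # medial parietal-like
  )
}

#' Plant a spatial covariance pattern in a template
#'
#' Sums isotropic Gaussian blobs (truncated at 3 SD), then mean-centers over
#' the brain mask and scales to unit Euclidean norm, so the planted pattern
#' obeys the same zero-mean/unit-norm convention as a derived pattern.
#'
#' @param template A [make_template()] result.
#' @param blobs List of [pattern_blob()]s; all centers must lie inside the
#'   brain mask.
#' @return 3D array: pattern values over the mask (zero outside).
#' @export
make_planted_pattern <- function(template, blobs = default_pattern_spec(template)) {
  mask <- template$brain_mask
  dm <- template$grid_shape
  sp <- template$spacing_mm
  ax <- lapply(1:3, function(a) (seq_len(dm[a]) - 0.5) * sp[a])

  field <- array(0, dm)
  for (b in blobs) {
    vox <- pmin(pmax(round(b$center_mm / sp + 0.5), 1), dm)
    if (!mask$indicator[vox[1], vox[2], vox[3]])
      stop("blob center lies outside the brain mask")
    if (b$amplitude == 0) next
    d2 <- outer(outer((ax[[1]] - b$center_mm[1])^2,
                      (ax[[2]] - b$center_mm[2])^2, `+`),
                (ax[[3]] - b$center_mm[3])^2, `+`)
    g <- exp(-d2 / (2 * b$radius_mm^2))
    g[d2 > (3 * b$radius_mm)^2] <- 0  # truncate at 3 SD
    field <- field + b$polarity * b$amplitude * g
  }
  idx <- mask_indices(mask)
  v <- field[idx]
  v <- v - mean(v)
  nrm <- sqrt(sum(v^2))
  if (nrm < 1e-12) stop("planted pattern is identically zero")
  out <- array(0, dm)
  out[idx] <- v / nrm
  out
}

#' Cohort generation settings
#'
#' Defaults mirror the derivation cohorts of the study the package models
#' (49 controls, 64 patients) with a patient expression distribution of mean
#' `delta = 1.3` and SD `tau = 0.9`, echoing the observed patient score
#' distribution; noise magnitudes are fixture choices (see the methods
#' vignette).
#'
#' @param n_control,n_patient Group sizes (>= 3 each).
#' @param delta Mean planted expression in patients (controls have mean 0).
#' @param tau Patient expression SD (controls have SD 1).
#' @param sigma_noise Voxel-wise log-intensity noise SD.
#' @param sigma_global Subject global log-offset SD (multiplicative scaling).
#' @param seed RNG seed; identical seeds give bitwise-identical cohorts.
#' @export
cohort_config <- function(n_control = 49, n_patient = 64, delta = 1.3,
                          tau = 0.9, sigma_noise = 0.01, sigma_global = 0.2,
                          seed = 1) {
  if (n_control < 3 || n_patient < 3)
    stop("need at least 3 subjects per group")
  if (any(c(tau, sigma_noise, sigma_global) < 0))
    stop("standard deviations must be non-negative")
  list(n_control = as.integer(n_control), n_patient = as.integer(n_patient),
       delta = delta, tau = tau, sigma_noise = sigma_noise,
       sigma_global = sigma_global, seed = as.integer(seed))
}

#' Simulate a brain-PET cohort with a planted covariance pattern
#'
#' Generative model, per subject s and in-mask voxel v:
#' \deqn{y_{sv} = \exp(\mu_v + \alpha_s + z_s p_v + \epsilon_{sv})}
#' with expression scores \eqn{z_s \sim N(0,1)} for controls and
#' \eqn{N(\delta, \tau^2)} for patients, global scaling offsets
#' \eqn{\alpha_s \sim N(0, \sigma_g^2)}, and voxel noise
#' \eqn{\epsilon_{sv} \sim N(0, \sigma_n^2)}. Voxels outside the brain mask
#' are zero. The multiplicative subject scaling \eqn{e^{\alpha_s}} is exactly
#' what SSM-PCA's log transform + row centering removes.
#'
#' @param template A [make_template()] result.
#' @param pattern 3D pattern array from [make_planted_pattern()].
#' @param config A [cohort_config()].
#' @return A `synthetic_cohort`: `scans` (list of [pet_scan()]), `labels`
#'   (factor control/patient), `ids`, `true_scores` (planted z per subject),
#'   `pattern_truth` (the pattern array), and the `template`.
#' @export
simulate_cohort <- function(template, pattern = make_planted_pattern(template),
                            config = cohort_config()) {
  mask <- template$brain_mask
  idx <- mask_indices(mask)
  stopifnot(identical(dim(pattern), template$grid_shape))
  n_c <- config$n_control; n_p <- config$n_patient
  set.seed(config$seed)

  z <- c(stats::rnorm(n_c, 0, 1), stats::rnorm(n_p, config$delta, config$tau))
  alpha <- stats::rnorm(n_c + n_p, 0, config$sigma_global)
  labels <- factor(rep(c("control", "patient"), c(n_c, n_p)),
                   levels = c("control", "patient"))
  ids <- c(sprintf("ctrl%03d", seq_len(n_c)), sprintf("pat%03d", seq_len(n_p)))

  mu_m <- template$mu[idx]
  p_m <- pattern[idx]
  scans <- vector("list", n_c + n_p)
  for (s in seq_along(scans)) {
    eps <- stats::rnorm(length(idx), 0, config$sigma_noise)
    vol <- array(0, template$grid_shape)
    vol[idx] <- exp(mu_m + alpha[s] + z[s] * p_m + eps)
    scans[[s]] <- pet_scan(vol, template$spacing_mm, id = ids[s])
  }
  structure(
    list(scans = scans, labels = labels, ids = ids, true_scores = z,
         pattern_truth = pattern, template = template, config = config),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d controls + %d patients, grid %s\n",
              sum(x$labels == "control"), sum(x$labels == "patient"),
              paste(x$template$grid_shape, collapse = "x")))
  invisible(x)
}

#' A solid (lesion or organ) of a whole-body phantom
#'
#' @param center_mm Center in mm; voxel centers sit at
#'   `(index - 0.5) * spacing`, so a center on the voxel-corner lattice gives
#'   an exact, unambiguous voxel count for axis-aligned boxes.
#' @param semi_axes_mm Ellipsoid semi-axes, or half-widths for `shape="box"`.
#' @param suv Uptake painted inside the solid.
#' @param shape `"ellipsoid"` (membership: voxel center inside or on the
#'   surface) or `"box"` (membership: strictly within all half-widths).
#' @export
phantom_solid <- function(center_mm, semi_axes_mm, suv,
                          shape = c("ellipsoid", "box")) {
  shape <- match.arg(shape)
  stopifnot(length(center_mm) == 3L, length(semi_axes_mm) == 3L,
            all(semi_axes_mm > 0), suv >= 0)
  list(center_mm = as.numeric(center_mm),
       semi_axes_mm = as.numeric(semi_axes_mm),
       suv = as.numeric(suv), shape = shape)
}

#' Whole-body SUV phantom specification
#'
#' @param grid_shape,spacing_mm Grid geometry.
#' @param background_suv Background uptake (must be below every lesion SUV).
#' @param lesions List of [phantom_solid()]s: the FDG-avid lesions (truth
#'   labels 1..K).
#' @param organs List of [phantom_solid()]s: physiological-uptake organs
#'   (brain, myocardium, bladder, kidney ...), truth codes 1001, 1002, ...;
#'   meant to be excluded from lesion segmentation downstream.
#' @export
body_phantom_spec <- function(grid_shape, spacing_mm, background_suv = 0.5,
                              lesions = list(), organs = list()) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            length(spacing_mm) == 3L, all(spacing_mm > 0),
            background_suv >= 0)
  for (l in lesions)
    if (l$suv <= background_suv)
      stop("lesion SUV must exceed the background SUV")
  list(grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
       background_suv = background_suv, lesions = lesions, organs = organs)
}

solid_membership <- function(solid, grid_shape, spacing_mm) {
  ax <- lapply(1:3, function(a) (seq_len(grid_shape[a]) - 0.5) * spacing_mm[a])
  if (solid$shape == "box") {
    inside <- outer(outer(
      abs(ax[[1]] - solid$center_mm[1]) < solid$semi_axes_mm[1],
      abs(ax[[2]] - solid$center_mm[2]) < solid$semi_axes_mm[2], `&`),
      abs(ax[[3]] - solid$center_mm[3]) < solid$semi_axes_mm[3], `&`)
  } else {
    d2 <- outer(outer(((ax[[1]] - solid$center_mm[1]) / solid$semi_axes_mm[1])^2,
                      ((ax[[2]] - solid$center_mm[2]) / solid$semi_axes_mm[2])^2,
                      `+`),
                ((ax[[3]] - solid$center_mm[3]) / solid$semi_axes_mm[3])^2, `+`)
    inside <- d2 <= 1
  }
  if (!any(inside)) stop("phantom solid contains no voxel centers")
  inside
}

#' Voxelize a whole-body SUV phantom with ground-truth labels
#'
#' Paints each solid at its SUV over a uniform background; a voxel belongs to
#' a solid iff its center lies inside it, which makes ground-truth volumes
#' exact voxel counts. Any overlap between painted solids is an error so the
#' truth labeling stays unambiguous.
#'
#' @param spec A [body_phantom_spec()].
#' @return List with `scan` (a SUV [pet_scan()]) and `truth` (integer array:
#'   0 background, 1..K lesions, 1000+j organs).
#' @export
simulate_body_phantom <- function(spec) {
  vol <- array(spec$background_suv, spec$grid_shape)
  truth <- array(0L, spec$grid_shape)
  paint <- function(solid, code) {
    inside <- solid_membership(solid, spec$grid_shape, spec$spacing_mm)
    if (any(truth[inside] != 0L))
      stop("phantom solids overlap; truth labels would be ambiguous")
    truth[inside] <<- code
    vol[inside] <<- solid$suv
  }
  for (k in seq_along(spec$lesions)) paint(spec$lesions[[k]], k)
  for (j in seq_along(spec$organs)) paint(spec$organs[[j]], 1000L + j)
  list(scan = pet_scan(vol, spec$spacing_mm, id = "phantom", units = "SUV"),
       truth = truth)
}
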