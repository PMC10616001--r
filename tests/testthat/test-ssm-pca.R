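# Minimal subject_matrix wrapper for algebraic hand examples that do not
# need scans or a mask.
toy_subject_matrix <- function(x, labels = NULL) {
  if (is.null(labels))
    labels <- factor(rep(c("control", "patient"), length.out = nrow(x)),
                     levels = c("control", "patient"))
  structure(list(x = x, labels = labels,
                 ids = paste0("s", seq_len(nrow(x))), mask = NULL,
                 fingerprint = "toy"),
            class = "subject_matrix")
}

test_that("build_matrix assembles log profiles and enforces group sizes", {
  co <- small_cohort(seed = 2, n_control = 3, n_patient = 3)
  mask <- co$template$brain_mask
  sm <- build_matrix(co$scans, mask, co$labels)
  expect_identical(dim(sm$x), c(6L, mask$n_voxels))
  # row = log of globally normalized scan, in mask ordering
  l1 <- log_transform(normalize_global(co$scans[[1]], mask), mask)
  expect_equal(unname(sm$x[1, ]), l1, tolerance = 1e-12)
  expect_error(build_matrix(co$scans[c(1, 2, 4, 5, 6)], mask,
                            co$labels[c(1, 2, 4, 5, 6)]), "at least 3")
})

test_that("double-centering matches the hand-computed example", {
  rp <- double_center(toy_subject_matrix(matrix(c(1, 3, 2, 5), 2)))
  expect_equal(unname(rp$srp),
               matrix(c(0.25, -0.25, -0.25, 0.25), 2), tolerance = 1e-12)
  expect_equal(unname(rp$gmp), c(-0.75, 0.75), tolerance = 1e-12)
})

test_that("double-centered residuals have zero row and column means", {
  set.seed(4)
  x <- matrix(rnorm(9 * 40, mean = 5), 9, 40)
  rp <- double_center(toy_subject_matrix(x))
  expect_lt(max(abs(rowMeans(rp$srp))), 1e-8)
  expect_lt(max(abs(colMeans(rp$srp))), 1e-8)
  const <- double_center(toy_subject_matrix(matrix(2.5, 4, 7)))
  expect_lt(max(abs(const$srp)), 1e-12)
})

test_that("principal components solve the 2x2 example by hand", {
  rp <- double_center(toy_subject_matrix(matrix(c(1, 3, 2, 5), 2)))
  comp <- principal_components(rp)
  expect_identical(ncol(comp$loadings), 1L)
  expect_equal(abs(unname(comp$loadings[, 1])), c(1, 1) / sqrt(2),
               tolerance = 1e-12)
  expect_gt(comp$loadings[1, 1], 0)  # deterministic sign rule
  expect_equal(comp$vaf, 1, tolerance = 1e-12)
  expect_equal(unname(comp$subject_scores[, 1]),
               c(1, -1) * sqrt(2) / 4, tolerance = 1e-12)
})

test_that("subject-space eigen route agrees with the SVD route", {
  set.seed(7)
  x <- matrix(rnorm(8 * 50), 8, 50)
  rp <- double_center(toy_subject_matrix(x))
  comp <- principal_components(rp)

  # independent subject-space route: eigen of S S^T, loadings mapped back
  ev <- eigen(rp$srp %*% t(rp$srp), symmetric = TRUE)
  keep <- ev$values > 1e-10
  d <- sqrt(ev$values[keep])
  u <- ev$vectors[, keep, drop = FALSE]
  loadings2 <- t(rp$srp) %*% u %*% diag(1 / d, length(d))
  scores2 <- u %*% diag(d, length(d))
  for (k in seq_along(d)) {  # align to the package's sign convention
    i <- which.max(abs(loadings2[, k]))
    if (loadings2[i, k] < 0) {
      loadings2[, k] <- -loadings2[, k]; scores2[, k] <- -scores2[, k]
    }
  }
  expect_equal(unname(comp$loadings), unname(loadings2), tolerance = 1e-8)
  expect_equal(unname(comp$subject_scores), unname(scores2), tolerance = 1e-8)

  # orthonormal loadings and full-rank reconstruction
  expect_lt(max(abs(crossprod(comp$loadings) - diag(ncol(comp$loadings)))),
            1e-8)
  recon <- comp$subject_scores %*% t(comp$loadings)
  expect_lt(max(abs(recon - rp$srp)), 1e-6)

  expect_error(principal_components(
    double_center(toy_subject_matrix(matrix(1, 4, 6)))), "no variance")
})

test_that("variance fractions sum to one and decrease", {
  set.seed(8)
  rp <- double_center(toy_subject_matrix(matrix(rnorm(10 * 30), 10, 30)))
  comp <- principal_components(rp)
  expect_equal(sum(comp$vaf), 1, tolerance = 1e-12)
  expect_true(all(diff(comp$vaf) <= 1e-12))
})

test_that("derived pattern recovers planted truth on a small cohort", {
  fix <- small_derivation()
  d <- fix$derived; co <- fix$cohort
  idx <- which(d$mask$indicator)
  w_full <- array(0, co$template$grid_shape)
  w_full[idx] <- d$pattern$weights
  expect_gte(abs(cor(w_full[idx], co$pattern_truth[idx])), 0.9)
  expect_gte(cor(d$scores$raw, co$true_scores), 0.9)
  # unit-norm weights, patient > control raw means (sign convention)
  expect_equal(sqrt(sum(d$pattern$weights^2)), 1, tolerance = 1e-10)
  raw <- d$scores$raw
  expect_gt(mean(raw[d$scores$label == "patient"]),
            mean(raw[d$scores$label == "control"]))
})

test_that("control Z scores are standardized by construction", {
  d <- small_derivation()$derived
  zc <- d$scores$z[d$scores$label == "control"]
  expect_equal(mean(zc), 0, tolerance = 1e-10)
  expect_equal(sd(zc), 1, tolerance = 1e-10)
})

test_that("pooled Z convention keeps control mean at 0 with wider SD", {
  fix <- small_derivation()
  comp <- fix$derived$components
  pooled <- derive_pattern(comp, z_convention = "pooled")
  zc <- pooled$scores$z[pooled$scores$label == "control"]
  expect_equal(mean(zc), 0, tolerance = 1e-10)
  expect_lt(sd(zc), 1)  # combined-sample SD exceeds the control SD here
  expect_equal(pooled$pattern$weights, fix$derived$pattern$weights,
               tolerance = 1e-12)
})

test_that("swapping group labels negates the pattern and raw scores", {
  fix <- small_derivation()
  comp <- fix$derived$components
  swapped <- comp
  swapped$labels <- factor(
    ifelse(comp$labels == "control", "patient", "control"),
    levels = c("control", "patient"))
  d2 <- derive_pattern(swapped)
  expect_equal(d2$pattern$weights, -fix$derived$pattern$weights,
               tolerance = 1e-8)
  expect_equal(d2$scores$raw, -fix$derived$scores$raw, tolerance = 1e-8)
})

test_that("expression is invariant to global scaling of an input scan", {
  fix <- small_derivation()
  pat <- fix$derived$pattern
  s <- fix$cohort$scans[[4]]
  s10 <- pet_scan(s$values * 37, s$spacing_mm, id = s$id)
  expect_equal(tpr_score(pat, s10, smooth_fwhm_mm = 8),
               tpr_score(pat, s, smooth_fwhm_mm = 8), tolerance = 1e-10)
})

test_that("scan order does not change the derived pattern", {
  co <- small_cohort(seed = 3, n_control = 5, n_patient = 5)
  perm <- c(7, 1, 9, 3, 5, 2, 10, 4, 8, 6)
  d1 <- derive_covariance_pattern(co$scans, co$labels, fwhm_mm = 0)
  d2 <- derive_covariance_pattern(co$scans[perm], co$labels[perm],
                                  fwhm_mm = 0)
  expect_equal(d2$pattern$weights, d1$pattern$weights, tolerance = 1e-8)
  m <- match(d1$scores$id, d2$scores$id)
  expect_equal(d2$scores$raw[m], d1$scores$raw, tolerance = 1e-8)
})

test_that("pattern survives a save/load round trip", {
  fix <- small_derivation()
  dir <- withr::local_tempdir()
  save_pattern(fix$derived$pattern, dir)
  pat2 <- load_pattern(dir)
  expect_equal(pat2$weights, fix$derived$pattern$weights, tolerance = 1e-12)
  expect_equal(pat2$gmp, fix$derived$pattern$gmp, tolerance = 1e-12)
  expect_identical(pat2$fingerprint, fix$derived$pattern$fingerprint)
  s <- fix$cohort$scans[[1]]
  expect_equal(tpr_score(pat2, s, smooth_fwhm_mm = 8),
               tpr_score(fix$derived$pattern, s, smooth_fwhm_mm = 8),
               tolerance = 1e-10)
})
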