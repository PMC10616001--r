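test_that("peak detection finds isolated hot lesions and nothing else", {
  dm <- c(24, 24, 24); sp <- c(4, 4, 4)
  flat <- pet_scan(array(0.5, dm), sp, units = "SUV")
  expect_identical(nrow(detect_peaks(flat)), 0L)

  two <- simulate_body_phantom(body_phantom_spec(
    dm, sp, background_suv = 0.5,
    lesions = list(phantom_solid(c(24, 24, 24), c(8, 8, 8), 10),
                   phantom_solid(c(72, 72, 72), c(8, 8, 8), 12))))
  pk <- detect_peaks(two$scan)
  expect_identical(nrow(pk), 2L)
  # each reported peak lies inside the corresponding truth lesion,
  # ordered by decreasing SUV
  expect_identical(two$truth[pk$index[1]], 2L)
  expect_identical(two$truth[pk$index[2]], 1L)

  # a lesion under the exclusion mask is not reported
  pk1 <- detect_peaks(two$scan, exclusion_mask = two$truth == 2L)
  expect_identical(nrow(pk1), 1L)
  expect_identical(two$truth[pk1$index], 1L)

  # min_suv filters faint maxima
  expect_identical(nrow(detect_peaks(two$scan, min_suv = 15)), 0L)
})

test_that("isocontour segmentation applies the 41% threshold through connectivity", {
  # peak 20 -> inclusion threshold 8.2: 8.3 is in, 8.1 is out
  dm <- c(11, 11, 11)
  v <- array(0.5, dm)
  v[6, 6, 6] <- 20; v[7, 6, 6] <- 8.3; v[8, 6, 6] <- 8.1
  s <- pet_scan(v, c(4, 4, 4), units = "SUV")
  seg <- segment_lesion(s, c(6, 6, 6), fraction = 0.41)
  lin <- function(i, j, k)
    as.integer(i + (j - 1) * dm[1] + (k - 1) * dm[1] * dm[2])
  expect_setequal(seg, c(lin(6, 6, 6), lin(7, 6, 6)))

  # isolated single hot voxel is a 1-voxel lesion
  v2 <- array(0.5, dm); v2[3, 3, 3] <- 12
  seg2 <- segment_lesion(pet_scan(v2, c(4, 4, 4), units = "SUV"), c(3, 3, 3))
  expect_identical(seg2, lin(3, 3, 3))

  # a same-intensity region connected only diagonally is still one lesion
  v3 <- array(0.5, dm); v3[4, 4, 4] <- 9; v3[5, 5, 5] <- 9
  seg3 <- segment_lesion(pet_scan(v3, c(4, 4, 4), units = "SUV"), c(4, 4, 4))
  expect_setequal(seg3, c(lin(4, 4, 4), lin(5, 5, 5)))
})

test_that("the worked box lesion is segmented voxel-for-voxel", {
  bp <- box_phantom()
  seg <- segment_all(bp$scan)
  expect_identical(nrow(seg$lesions), 1L)
  expect_identical(which(seg$labels == 1L), which(bp$truth == 1L))
  expect_identical(seg$lesions$n_voxels, 1000L)

  bm <- burden_metrics(seg, bp$scan)
  expect_equal(bm$tmtv_ml, 64, tolerance = 1e-12)  # 1000 voxels x 0.064 mL
  expect_equal(bm$tlg, 640, tolerance = 1e-12)     # uniform SUV 10
  expect_identical(bm$suv_max, 10)
  expect_equal(bm$lg_tmtv, log10(64), tolerance = 1e-12)
})

test_that("multi-lesion phantoms segment to ground truth with exclusions", {
  dm <- c(32, 32, 32); sp <- c(4, 4, 4)
  ph <- simulate_body_phantom(body_phantom_spec(
    dm, sp, background_suv = 0.5,
    lesions = list(phantom_solid(c(32, 32, 32), c(10, 10, 10), 12),
                   phantom_solid(c(96, 32, 48), c(8, 12, 8), 9),
                   phantom_solid(c(48, 96, 96), c(12, 8, 10), 15)),
    organs = list(phantom_solid(c(96, 96, 32), c(12, 12, 12), 7))))
  excl <- ph$truth >= 1000L
  seg <- segment_all(ph$scan, exclusion_mask = excl)
  expect_identical(nrow(seg$lesions), 3L)
  # labels ordered by peak SUV: truth lesions 3 (15), 1 (12), 2 (9)
  expect_identical(which(seg$labels == 1L), which(ph$truth == 3L))
  expect_identical(which(seg$labels == 2L), which(ph$truth == 1L))
  expect_identical(which(seg$labels == 3L), which(ph$truth == 2L))
  # organ voxels never enter a lesion
  expect_true(all(seg$labels[excl] == 0L))
  # every lesion voxel is at or above 41% of its lesion peak
  for (r in seq_len(3)) {
    vox <- ph$scan$values[seg$labels == r]
    expect_true(all(vox >= 0.41 * seg$lesions$peak_suv[r]))
  }

  # everything excluded -> empty segmentation with zeroed metrics
  seg0 <- segment_all(ph$scan, exclusion_mask = ph$truth != 0L)
  expect_identical(nrow(seg0$lesions), 0L)
  bm0 <- burden_metrics(seg0, ph$scan)
  expect_identical(bm0$tmtv_ml, 0)
  expect_identical(bm0$tlg, 0)
  expect_true(is.na(bm0$lg_tmtv) && is.na(bm0$lg_tlg))
})

test_that("touching isocontours merge into one lesion led by the hotter peak", {
  dm <- c(21, 11, 11)
  v <- array(0.5, dm)
  v[8, 6, 6] <- 20
  v[9:12, 6, 6] <- 9    # bridge above both 41% thresholds
  v[13, 6, 6] <- 14
  s <- pet_scan(v, c(4, 4, 4), units = "SUV")
  seg <- segment_all(s)
  expect_identical(nrow(seg$lesions), 1L)
  expect_identical(seg$lesions$peak_suv, 20)
  expect_identical(seg$lesions$n_voxels, 6L)
})

test_that("TLG identity holds and TMTV is monotone in the fraction", {
  # smooth (non-flat) lesion profile
  dm <- c(24, 24, 24); sp <- c(4, 4, 4)
  ax <- (seq_len(dm[1]) - 0.5) * sp[1]
  d2 <- outer(outer((ax - 48)^2, (ax - 48)^2, `+`), (ax - 48)^2, `+`)
  v <- 0.5 + 11.5 * exp(-d2 / (2 * 12^2))
  s <- pet_scan(v, sp, units = "SUV")
  prev <- Inf
  for (f in c(0.2, 0.41, 0.6, 0.8, 0.95)) {
    seg <- segment_all(s, fraction = f)
    bm <- burden_metrics(seg, s)
    expect_equal(bm$tlg, bm$tmtv_ml * bm$suv_mean, tolerance = 1e-9)
    expect_lte(bm$tmtv_ml, prev)
    prev <- bm$tmtv_ml
  }
})

test_that("explicit seeds reproduce the semi-automatic workflow", {
  bp <- box_phantom()
  pk <- detect_peaks(bp$scan)
  seg_auto <- segment_all(bp$scan)
  seg_seed <- segment_all(bp$scan, seeds = pk$index)
  expect_identical(seg_seed$labels, seg_auto$labels)
})

test_that("brain glycolysis is volume times mean SUV and scales linearly", {
  dm <- c(20, 20, 20); sp <- c(5, 5, 5)  # 0.125 mL voxels
  mask <- pet_mask(array(rep(c(TRUE, FALSE), c(4000, 4000)), dm), sp)
  u <- pet_scan(array(1, dm), sp, units = "SUV")
  bg <- brain_glycolysis(u, mask)
  expect_equal(bg$tbg, mask$n_voxels * 0.125, tolerance = 1e-12)

  set.seed(9)
  v <- array(rexp(prod(dm)) + 0.2, dm)
  s1 <- pet_scan(v, sp, units = "SUV")
  s2 <- pet_scan(2 * v, sp, units = "SUV")
  b1 <- brain_glycolysis(s1, mask); b2 <- brain_glycolysis(s2, mask)
  expect_equal(b2$tbg, 2 * b1$tbg, tolerance = 1e-12)
  expect_equal(b1$tbg, b1$volume_ml * b1$suv_mean, tolerance = 1e-9)

  # linear-gradient field: closed-form mean over the mask
  g <- array(rep(seq_len(dm[1]), times = prod(dm[2:3])), dm)  # SUV = i
  mask_all <- pet_mask(array(TRUE, dm), sp)
  bg_g <- brain_glycolysis(pet_scan(g, sp, units = "SUV"), mask_all)
  expect_equal(bg_g$suv_mean, mean(seq_len(dm[1])), tolerance = 1e-12)
  expect_equal(bg_g$tbg, prod(dm) * 0.125 * 10.5, tolerance = 1e-9)
})
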