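# 26-neighborhood machinery. Arrays are padded with one border voxel so
# linear-index arithmetic never wraps across faces.
neighbor_offsets_26 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
}

pad_index <- function(idx, dm) {
  co <- arrayInd(idx, dm)
  dmp <- dm + 2L
  (co[, 1] + 1L) + co[, 2] * dmp[1] + co[, 3] * dmp[1] * dmp[2]
}

unpad_index <- function(pidx, dm) {
  dmp <- dm + 2L
  co0 <- pidx - 1L
  i <- co0 %% dmp[1]
  j <- (co0 %/% dmp[1]) %% dmp[2]
  k <- co0 %/% (dmp[1] * dmp[2])
  i + (j - 1L) * dm[1] + (k - 1L) * dm[1] * dm[2]
}

# Maximum over the 26 neighbors of every voxel (-Inf beyond the volume).
neighbor_max <- function(v) {
  dm <- dim(v)
  vp <- array(-Inf, dm + 2L)
  vp[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- v
  out <- array(-Inf, dm)
  for (r in seq_len(26)) {
    o <- neighbor_offsets_26()[r, ]
    out <- pmax(out, vp[(2 + o[1]):(dm[1] + 1 + o[1]),
                        (2 + o[2]):(dm[2] + 1 + o[2]),
                        (2 + o[3]):(dm[3] + 1 + o[3])])
  }
  out
}

# Connected component (26-connectivity) of `support` containing `seeds`.
# Returns linear voxel indices.
flood_fill_26 <- function(support, seeds) {
  dm <- dim(support)
  dmp <- dm + 2L
  sup <- array(FALSE, dmp)
  sup[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- support
  offs <- neighbor_offsets_26()
  poffs <- offs[, 1] + offs[, 2] * dmp[1] + offs[, 3] * dmp[1] * dmp[2]
  seeds <- pad_index(seeds, dm)
  seeds <- seeds[sup[seeds]]
  if (length(seeds) == 0L) return(integer(0))
  visited <- array(FALSE, dmp)
  visited[seeds] <- TRUE
  frontier <- seeds
  while (length(frontier) > 0L) {
    nb <- unique(as.vector(outer(poffs, frontier, `+`)))
    nb <- nb[sup[nb] & !visited[nb]]
    visited[nb] <- TRUE
    frontier <- nb
  }
  sort(unpad_index(which(visited), dm))
}

#' Detect candidate lesion peaks on a SUV volume
#'
#' Local maxima over the 26-neighborhood with SUV at or above `min_suv`,
#' outside an optional exclusion mask (physiological-uptake organs: brain,
#' myocardium, bladder, kidney). Flat-topped hot regions form plateaus of
#' tied maxima; each connected plateau is reported as a single peak, the
#' representative voxel being the first in the fixed column-major ordering.
#' This automatic seeding is a reproducible stand-in for manual VOI seeding;
#' explicit seeds can be given to [segment_all()] instead.
#'
#' @param scan A SUV [pet_scan()].
#' @param exclusion_mask Optional logical array or [pet_mask()]; candidate
#'   peaks inside it are dropped.
#' @param min_suv Minimum peak SUV (default 2.5).
#' @return data.frame: `i`, `j`, `k` (voxel indices), `index` (linear),
#'   `suv`; sorted by SUV descending, then linear index. Zero rows when
#'   nothing qualifies.
#' @export
detect_peaks <- function(scan, exclusion_mask = NULL, min_suv = 2.5) {
  v <- scan$values
  dm <- dim(v)
  excl <- array(FALSE, dm)
  if (!is.null(exclusion_mask)) {
    if (inherits(exclusion_mask, "pet_mask")) exclusion_mask <- exclusion_mask$indicator
    stopifnot(identical(dim(exclusion_mask), dm))
    excl <- exclusion_mask
  }
  cand <- (v >= neighbor_max(v)) & (v >= min_suv) & !excl
  empty <- data.frame(i = integer(0), j = integer(0), k = integer(0),
                      index = integer(0), suv = numeric(0))
  if (!any(cand)) return(empty)

  # one peak per connected plateau of candidates
  remaining <- cand
  rows <- list()
  while (any(remaining)) {
    seed <- which(remaining)[1]
    comp <- flood_fill_26(cand, seed)
    pk <- comp[v[comp] == max(v[comp])][1]
    rows[[length(rows) + 1L]] <- c(index = pk, suv = v[pk])
    remaining[comp] <- FALSE
  }
  m <- do.call(rbind, rows)
  co <- arrayInd(as.integer(m[, "index"]), dm)
  out <- data.frame(i = co[, 1], j = co[, 2], k = co[, 3],
                    index = as.integer(m[, "index"]), suv = m[, "suv"])
  out[order(-out$suv, out$index), , drop = FALSE]
}

#' Segment one lesion by a percentage-of-SUVmax isocontour
#'
#' The lesion is the 26-connected component, containing the peak, of voxels
#' with SUV at or above `fraction` times the peak SUV — the study protocol's
#' 41% isocontour.
#'
#' @param scan A SUV [pet_scan()].
#' @param peak Linear voxel index, or `c(i, j, k)`.
#' @param fraction Isocontour fraction of the peak SUV (default 0.41).
#' @return Sorted integer vector of linear voxel indices.
#' @export
segment_lesion <- function(scan, peak, fraction = 0.41) {
  v <- scan$values
  dm <- dim(v)
  if (length(peak) == 3L) peak <- peak[1] + (peak[2] - 1L) * dm[1] +
      (peak[3] - 1L) * dm[1] * dm[2]
  peak <- as.integer(peak)
  stopifnot(peak >= 1L, peak <= prod(dm), fraction > 0, fraction <= 1)
  flood_fill_26(v >= fraction * v[peak], peak)
}

#' Segment all FDG-avid lesions on a whole-body SUV volume
#'
#' Runs [detect_peaks()] (or takes explicit seed peaks), grows each lesion
#' with [segment_lesion()], and merges overlapping or touching segments into
#' a single lesion whose reported peak is the highest-SUV peak involved.
#' Final labels are deterministic: 1..K in order of decreasing peak SUV,
#' ties broken by the fixed voxel ordering.
#'
#' @inheritParams detect_peaks
#' @param fraction Isocontour fraction (default 0.41).
#' @param seeds Optional integer vector of linear voxel indices to use as
#'   peaks instead of automatic detection ("semi-automatic" mode).
#' @return A `lesion_segmentation`: `labels` (integer array, 0 background),
#'   `lesions` (data.frame: label, peak i/j/k, peak_suv, n_voxels,
#'   volume_ml), `fraction`, `voxel_volume_ml`.
#' @export
segment_all <- function(scan, exclusion_mask = NULL, fraction = 0.41,
                        min_suv = 2.5, seeds = NULL) {
  v <- scan$values
  dm <- dim(v)
  if (is.null(seeds)) {
    peaks <- detect_peaks(scan, exclusion_mask, min_suv)
  } else {
    seeds <- as.integer(seeds)
    peaks <- data.frame(arrayInd(seeds, dm))
    names(peaks) <- c("i", "j", "k")
    peaks$index <- seeds
    peaks$suv <- v[seeds]
    peaks <- peaks[order(-peaks$suv, peaks$index), , drop = FALSE]
  }
  lab <- array(0L, dm)
  peak_of <- list()  # per provisional label: linear index of its top peak
  nlab <- 0L
  for (r in seq_len(nrow(peaks))) {
    seg <- segment_lesion(scan, peaks$index[r], fraction)
    hit <- setdiff(unique(lab[seg]), 0L)
    if (length(hit) == 0L) {
      nlab <- nlab + 1L
      lab[seg] <- nlab
      peak_of[[nlab]] <- peaks$index[r]
    } else {
      # peaks are processed in decreasing SUV, so the smallest existing
      # label carries the highest peak; fold everything into it
      target <- min(hit)
      lab[seg] <- target
      for (h in setdiff(hit, target)) lab[lab == h] <- target
    }
  }
  keep <- sort(unique(lab[lab > 0L]))
  vox_ml <- prod(scan$spacing_mm) / 1000
  if (length(keep) == 0L) {
    lesions <- data.frame(label = integer(0), i = integer(0), j = integer(0),
                          k = integer(0), peak_suv = numeric(0),
                          n_voxels = integer(0), volume_ml = numeric(0))
  } else {
    pk <- vapply(keep, function(h) peak_of[[h]], integer(1))
    ord <- order(-v[pk], pk)
    keep <- keep[ord]; pk <- pk[ord]
    relab <- array(0L, dm)
    for (new in seq_along(keep)) relab[lab == keep[new]] <- new
    lab <- relab
    co <- arrayInd(pk, dm)
    nv <- as.integer(tabulate(lab[lab > 0L], nbins = length(keep)))
    lesions <- data.frame(label = seq_along(keep), i = co[, 1], j = co[, 2],
                          k = co[, 3], peak_suv = v[pk], n_voxels = nv,
                          volume_ml = nv * vox_ml)
  }
  structure(
    list(labels = lab, lesions = lesions, fraction = fraction,
         voxel_volume_ml = vox_ml),
    class = "lesion_segmentation"
  )
}

#' @export
print.lesion_segmentation <- function(x, ...) {
  cat(sprintf("<lesion_segmentation> %d lesion(s), %.1f mL total (%.0f%% isocontour)\n",
              nrow(x$lesions), sum(x$lesions$volume_ml), 100 * x$fraction))
  invisible(x)
}

#' Tumor burden metrics from a lesion segmentation
#'
#' TMTV is the summed volume of all segmented lesion VOIs; TLG is the
#' product of TMTV and the SUVmean over all lesion voxels. Base-10 log
#' transforms of both are reported as `NA` when no lesion was segmented
#' (never `-Inf`).
#'
#' @param seg A [segment_all()] result.
#' @param scan The SUV [pet_scan()] the segmentation came from.
#' @return A list: `tmtv_ml`, `suv_max`, `suv_mean`, `tlg`, `lg_tmtv`,
#'   `lg_tlg`, `n_lesions`.
#' @export
burden_metrics <- function(seg, scan) {
  stopifnot(inherits(seg, "lesion_segmentation"),
            identical(dim(seg$labels), dim(scan$values)))
  vox <- seg$labels > 0L
  n <- sum(vox)
  if (n == 0L) {
    return(list(tmtv_ml = 0, suv_max = NA_real_, suv_mean = NA_real_,
                tlg = 0, lg_tmtv = NA_real_, lg_tlg = NA_real_,
                n_lesions = 0L))
  }
  suv <- scan$values[vox]
  tmtv <- n * seg$voxel_volume_ml
  suv_mean <- mean(suv)
  tlg <- tmtv * suv_mean
  list(tmtv_ml = tmtv, suv_max = max(suv), suv_mean = suv_mean, tlg = tlg,
       lg_tmtv = log10(tmtv), lg_tlg = log10(tlg),
       n_lesions = nrow(seg$lesions))
}

#' Whole-brain glycolysis metrics
#'
#' Total brain glycolysis (TBG) is the product of the total brain metabolic
#' volume and the brain SUVmean. By default the metabolic volume is the full
#' brain-mask volume; an optional SUV threshold restricts both the volume
#' and the mean to supra-threshold voxels.
#'
#' @param scan A SUV-calibrated brain [pet_scan()].
#' @param mask Brain [pet_mask()].
#' @param suv_threshold Optional minimum SUV defining "metabolic" voxels.
#' @return A list: `volume_ml`, `suv_max`, `suv_mean`, `tbg`.
#' @export
brain_glycolysis <- function(scan, mask, suv_threshold = NULL) {
  check_same_grid(scan, mask)
  v <- scan$values[mask$indicator]
  if (!is.null(suv_threshold)) v <- v[v >= suv_threshold]
  if (length(v) == 0L) stop("no brain voxels above the SUV threshold")
  vol <- length(v) * mask$voxel_volume_ml
  list(volume_ml = vol, suv_max = max(v), suv_mean = mean(v),
       tbg = vol * mean(v))
}
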