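default_run_config <- function() {
  list(
    seed = 7L,
    out_dir = "covpet_run",
    grid_shape = c(64L, 64L, 48L),
    spacing_mm = c(2, 2, 2),
    cohort = list(n_control = 49L, n_patient = 64L, delta = 1.3, tau = 0.9,
                  sigma_noise = 0.01, sigma_global = 0.2),
    preprocess = list(fwhm_mm = 10, mask_fraction = 0.2),
    derive = list(vaf_cutoff = 0.5, z_convention = "control"),
    burden = list(fraction = 0.41, min_suv = 2.5),
    stages = list(simulate = TRUE, derive = TRUE, score = TRUE,
                  burden = TRUE, stats = TRUE),
    mask_file = NULL,
    write_scans = FALSE
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Write the demo pipeline configuration
#'
#' Emits a YAML config for the default synthetic study: 49 controls and 64
#' patients on a 64x64x48 grid at 2 mm spacing, 10 mm smoothing, 41%
#' isocontour. Re-emitting produces an identical file.
#'
#' @param out_dir Writable directory; the config is written as
#'   `demo_config.yaml` inside it.
#' @return Path to the written config, invisibly.
#' @export
make_demo_config <- function(out_dir) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  cfg <- default_run_config()
  cfg$out_dir <- file.path(out_dir, "artifacts")
  cfg$mask_file <- NULL
  path <- file.path(out_dir, "demo_config.yaml")
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Run the full synthetic-study pipeline
#'
#' Orchestrates simulate -> preprocess/derive -> score -> burden -> stats
#' from one config (a list or a YAML/JSON file path), writing a pattern
#' sidecar, `scores.csv`, `burden.json`, `stats.json` and `run.log` into
#' `config$out_dir`. All randomness flows from `config$seed` through the
#' cohort generator; the remaining stages are deterministic, so repeated
#' runs with one seed produce bitwise-identical CSV/JSON artifacts. On any
#' error the partially written artifacts are removed before the error
#' propagates.
#'
#' @param config Config list (see [make_demo_config()] for the schema) or a
#'   path to a YAML/JSON file.
#' @return The artifact directory path, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  cfg <- merge_config(default_run_config(), config)
  if (!is.null(cfg$mask_file) && !file.exists(cfg$mask_file))
    stop("mask file not found: ", cfg$mask_file)

  out <- cfg$out_dir
  pre_existing <- dir.exists(out)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  made <- character(0)
  note <- function(...) { p <- file.path(out, ...); made <<- c(made, p); p }
  logline <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message(msg)
    logline <<- c(logline, msg)
  }

  run <- function() {
    say("covpet pipeline, seed %d", cfg$seed)
    template <- make_template(cfg$grid_shape, cfg$spacing_mm)
    pattern_truth <- make_planted_pattern(template)
    cohort <- NULL
    derived <- NULL

    if (isTRUE(cfg$stages$simulate)) {
      cc <- cohort_config(n_control = cfg$cohort$n_control,
                          n_patient = cfg$cohort$n_patient,
                          delta = cfg$cohort$delta, tau = cfg$cohort$tau,
                          sigma_noise = cfg$cohort$sigma_noise,
                          sigma_global = cfg$cohort$sigma_global,
                          seed = cfg$seed)
      cohort <- simulate_cohort(template, pattern_truth, cc)
      say("simulated %d scans on a %s grid", length(cohort$scans),
          paste(cfg$grid_shape, collapse = "x"))
      if (isTRUE(cfg$write_scans)) {
        sdir <- note("scans")
        dir.create(sdir, showWarnings = FALSE)
        for (s in cohort$scans)
          write_scan(s, file.path(sdir, paste0(s$id, ".nii.gz")))
      }
    }

    if (isTRUE(cfg$stages$derive)) {
      if (is.null(cohort)) stop("derive stage needs the simulate stage")
      mask <- if (!is.null(cfg$mask_file)) {
        mvol <- read_scan(cfg$mask_file)
        pet_mask(mvol$values > 0.5, mvol$spacing_mm)
      } else NULL
      derived <- derive_covariance_pattern(
        cohort$scans, cohort$labels, mask = mask,
        fwhm_mm = cfg$preprocess$fwhm_mm,
        mask_fraction = cfg$preprocess$mask_fraction,
        vaf_cutoff = cfg$derive$vaf_cutoff,
        z_convention = cfg$derive$z_convention)
      save_pattern(derived$pattern, note("pattern"))
      say("derived pattern over %d voxels (components %s)",
          length(derived$pattern$weights),
          paste(derived$pattern$component_indices, collapse = ","))
    }

    if (isTRUE(cfg$stages$score)) {
      if (is.null(derived)) stop("score stage needs the derive stage")
      sc <- derived$scores
      sc$timepoint <- "baseline"
      utils::write.csv(sc[, c("id", "label", "timepoint", "raw", "z")],
                       note("scores.csv"), row.names = FALSE)
      say("scored %d subjects", nrow(sc))
    }

    if (isTRUE(cfg$stages$burden)) {
      phantom <- simulate_body_phantom(demo_body_spec())
      excl <- phantom$truth >= 1000L
      seg <- segment_all(phantom$scan, exclusion_mask = excl,
                         fraction = cfg$burden$fraction,
                         min_suv = cfg$burden$min_suv)
      bm <- burden_metrics(seg, phantom$scan)
      brain <- pet_mask(phantom$truth == 1001L, phantom$scan$spacing_mm)
      bg <- brain_glycolysis(phantom$scan, brain)
      jsonlite::write_json(list(tumor = bm, brain = bg),
                           note("burden.json"), auto_unbox = TRUE,
                           digits = NA)
      say("burden: %d lesion(s), TMTV %.1f mL, TLG %.1f",
          bm$n_lesions, bm$tmtv_ml, bm$tlg)
    }

    if (isTRUE(cfg$stages$stats)) {
      if (is.null(derived)) stop("stats stage needs the derive stage")
      sc <- derived$scores
      grp <- compare_two(sc$z[sc$label == "control"],
                         sc$z[sc$label == "patient"])
      w_full <- array(0, template$grid_shape)
      w_full[mask_indices(derived$mask)] <- derived$pattern$weights
      on_mask <- mask_indices(derived$mask)
      r_pattern <- stats::cor(w_full[on_mask], cohort$pattern_truth[on_mask])
      r_scores <- stats::cor(sc$raw, cohort$true_scores)
      stats_out <- list(
        group_comparison = list(test = grp$test, statistic = grp$statistic,
                                p = grp$p),
        pattern_recovery_r = abs(r_pattern),
        score_recovery_r = r_scores,
        pattern_recovery_pass = abs(r_pattern) >= 0.9 && r_scores >= 0.9,
        seed = cfg$seed)
      jsonlite::write_json(stats_out, note("stats.json"),
                           auto_unbox = TRUE, digits = NA)
      say("recovery: |r(weights, truth)| = %.3f, r(scores, truth) = %.3f",
          abs(r_pattern), r_scores)
    }

    writeLines(c(logline,
                 sprintf("R %s, covpet %s", getRversion(),
                         as.character(utils::packageVersion("covpet"))),
                 format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               file.path(out, "run.log"))
    invisible(out)
  }

  tryCatch(run(), error = function(e) {
    unlink(made, recursive = TRUE)
    unlink(file.path(out, "run.log"))
    if (!pre_existing && length(list.files(out)) == 0L)
      unlink(out, recursive = TRUE)
    stop(e)
  })
}

# Fixed whole-body phantom used by the pipeline's burden stage: three
# ellipsoidal lesions plus a brain-like organ that the segmentation must
# exclude. Geometry is deterministic.
demo_body_spec <- function() {
  sp <- c(4, 4, 4)
  body_phantom_spec(
    grid_shape = c(48, 48, 72), spacing_mm = sp, background_suv = 0.5,
    lesions = list(
      phantom_solid(c(60, 80, 120), c(16, 14, 18), suv = 12),
      phantom_solid(c(130, 100, 160), c(10, 10, 10), suv = 8),
      phantom_solid(c(90, 60, 200), c(8, 12, 8), suv = 20)
    ),
    organs = list(
      phantom_solid(c(96, 96, 250), c(30, 30, 26), suv = 7)  # brain-like
    )
  )
}

#' Pattern-recovery experiment on one synthetic cohort
#'
#' Generates a cohort under the default study conditions (49 controls, 64
#' patients, planted patient expression 1.3 +/- 0.9), derives the pattern
#' end to end (smoothing, data-driven mask, SSM-PCA, discriminant
#' combination) and measures how well the known truth is recovered.
#'
#' @param seed Cohort RNG seed.
#' @param grid_shape,spacing_mm Template geometry.
#' @param config Optional [cohort_config()] override (its `seed` is replaced
#'   by `seed`).
#' @param fwhm_mm Smoothing FWHM passed to [derive_covariance_pattern()].
#' @return List: `r_weights` (|Pearson r| between derived weights and the
#'   planted pattern over the analysis mask), `r_scores` (Pearson r between
#'   derivation raw scores and planted subject expressions), plus the
#'   derived objects for inspection.
#' @export
recovery_experiment <- function(seed, grid_shape = c(64, 64, 48),
                                spacing_mm = c(2, 2, 2), config = NULL,
                                fwhm_mm = 10) {
  template <- make_template(grid_shape, spacing_mm)
  truth <- make_planted_pattern(template)
  if (is.null(config)) config <- cohort_config()
  config$seed <- as.integer(seed)
  cohort <- simulate_cohort(template, truth, config)
  d <- derive_covariance_pattern(cohort$scans, cohort$labels,
                                 fwhm_mm = fwhm_mm)
  idx <- mask_indices(d$mask)
  w_full <- array(0, grid_shape)
  w_full[idx] <- d$pattern$weights
  list(r_weights = abs(stats::cor(w_full[idx], truth[idx])),
       r_scores = stats::cor(d$scores$raw, cohort$true_scores),
       derived = d, cohort = cohort)
}
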