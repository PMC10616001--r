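# covpet

Metabolic covariance pattern analysis and tumor burden quantification for
FDG-PET, with a fully synthetic test bed.

## The problem

In systemic lymphoma (diffuse large B-cell lymphoma in particular), the
brain's glucose metabolism reorganizes even without CNS involvement: FDG-PET
shows relatively increased uptake in cerebellum, brainstem and deep gray
structures together with relatively decreased parieto-occipital and
cingulate uptake, and the whole-brain FDG "input" falls as the tumor
competes for glucose. Two quantitative toolsets are needed to study this:

1. **Spatial covariance analysis of brain PET.** The scaled subprofile model
   with principal component analysis (SSM-PCA) derives a *disease-related
   covariance pattern* from control and patient scans, and a *topographic
   profile rating* (TPR) scores any new scan's expression of that fixed
   pattern as a single Z-scored number.
2. **Whole-body tumor burden.** FDG-avid lesions are segmented at a 41%
   of-lesion-SUVmax isocontour; total metabolic tumor volume (TMTV), total
   lesion glycolysis (TLG = TMTV × SUVmean) and total brain glycolysis
   (TBG = brain metabolic volume × brain SUVmean) summarize disease load
   and brain uptake.

`covpet` implements both, plus the statistical battery such studies run
(gated two-sample/three-group comparisons, Pearson χ² without continuity
correction, Pearson/Spearman correlation, and Steiger's Z for dependent
correlation coefficients). Because clinical scans cannot be redistributed,
the package ships a synthetic-cohort generator that plants a known
covariance pattern in a log-linear generative model, and lesion phantoms
with exact voxel-counted ground truth, so every stage is testable end to
end.

## The model

For subject *s* and brain voxel *v*, intensities follow the log-linear SSM
form

    y_sv = exp(mu_v + alpha_s + z_s * p_v + eps_sv)

where `mu_v` is a template profile, `alpha_s` a subject global scaling
offset, `p_v` the pattern topography (zero mean, unit norm over the brain
mask), `z_s` the subject's pattern expression, and `eps_sv` voxel noise.
Derivation log-transforms globally normalized scans, removes `alpha_s` by
row centering and `mu_v`-like structure by column centering (the stored
group mean profile, GMP), extracts principal components of the residuals,
and combines the leading components (cumulative variance ≥ 50%) with a
Fisher discriminant to maximize patient/control separation. Prospective
scoring of one scan is the inner product of its residual profile with the
pattern weights, Z-scored against the control reference.

## Worked example

```r
library(covpet)

# synthetic study: 49 controls, 64 patients, planted pattern
template <- make_template(c(64, 64, 48), c(2, 2, 2))
truth    <- make_planted_pattern(template)
cohort   <- simulate_cohort(template, truth, cohort_config(seed = 1))

d <- derive_covariance_pattern(cohort$scans, cohort$labels, fwhm_mm = 10)
d$pattern
#> <covariance_pattern> 85631 voxels, components 1 (VAF 0.97),
#>   z_ref -0.7467 +/- 0.8028 [control]

idx <- which(d$mask$indicator)
w <- array(0, dim(truth)); w[idx] <- d$pattern$weights
cor(w[idx], truth[idx])          # pattern topography recovered
#> [1] 0.9472949
cor(d$scores$raw, cohort$true_scores)  # planted expressions recovered
#> [1] 0.9999524

# prospective scoring of a held-out scan
held <- simulate_cohort(template, truth, cohort_config(seed = 99))
tpr_score(d$pattern, held$scans[[60]], smooth_fwhm_mm = 10)
#> [1] -0.2207179   # raw expression, Z-scored via zscore(., d$pattern$z_ref)

# tumor burden on a phantom with exact ground truth
bp  <- simulate_body_phantom(body_phantom_spec(
  c(24, 24, 24), c(4, 4, 4), background_suv = 0.5,
  lesions = list(phantom_solid(c(48, 48, 48), c(20, 20, 20), 10, "box"))))
bm  <- burden_metrics(segment_all(bp$scan), bp$scan)
c(bm$tmtv_ml, bm$tlg)
#> [1]  64 640        # 1000 voxels x 0.064 mL; TLG = 64 x SUVmean 10

# the statistics the study reports
chi_square_2x2(rbind(c(28, 36), c(24, 15)))
#> Pearson chi-square: statistic = 3.068, p = 0.07987
compare_dependent_correlations(0.6, 0.4, 0.7, n = 60)
#> Steiger Z (dependent correlations): statistic = 2.334, p = 0.0196
```

The derived |r| ≈ 0.95 against the planted topography (the 10 mm smoothing
kernel slightly blurs the truth) and r ≈ 0.9999 for the expression scores
hold across seeds; `recovery_experiment(seed)` reruns the whole experiment
for any seed.

A full pipeline run (simulate → derive → score → burden → stats) is driven
by one config: `make_demo_config("demo")` then
`run_pipeline("demo/demo_config.yaml")`, or from a shell via the thin CLI
`inst/exec/covpet run demo/demo_config.yaml`. Outputs (pattern sidecar
NIfTI+JSON, `scores.csv`, `burden.json`, `stats.json`) are bitwise
reproducible under a fixed seed.

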