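---
title: "Methods: covariance patterns, burden metrics, and the synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: covariance patterns, burden metrics, and the synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(covpet)
```

This vignette is the package's own account of its methods: the generative
and analysis models, the tunable parameters and why their defaults are what
they are, what the synthetic data do and do not emulate, and the numerical
conventions that make results reproducible bit for bit.

## The SSM-PCA model

PET intensities are intrinsically non-quantitative across subjects: dose,
uptake time and scanner calibration multiply every voxel by an unknown
subject factor. The scaled subprofile model removes this multiplicative
nuisance by working in the log domain. The package's generative model (and
the assumption under which the analysis is exact) is, for subject $s$ and
brain voxel $v$,

$$ y_{sv} = \exp(\mu_v + \alpha_s + z_s\, p_v + \varepsilon_{sv}), $$

with a template log-profile $\mu_v$, subject scaling offset $\alpha_s$,
pattern topography $p_v$ (zero mean, unit Euclidean norm over the brain
mask), subject expression $z_s$, and voxel noise $\varepsilon_{sv}$.

Analysis proceeds in five steps:

1. **Smoothing** (`smooth_gaussian`): separable Gaussian, FWHM 10 mm by
   default, matching common brain-PET practice; $\sigma$ per axis is
   FWHM$/(2\sqrt{2\ln 2})$ divided by the voxel spacing, so anisotropic
   grids are handled. The truncated kernel (4 SD) is renormalized at the
   volume boundary, so a constant volume passes through unchanged.
2. **Global normalization** (`normalize_global`): division by the scan's
   mean over the analysis mask (the whole brain as reference region). The
   mean is used rather than another location statistic; this is
   configurable in effect because any masked statistic that scales linearly
   would cancel identically in the later row centering.
3. **Log transform** (`log_transform`) over the mask, in a fixed
   column-major voxel ordering that the pattern records via a mask
   fingerprint. Values below a floor ($10^{-6}$ of the masked mean) are
   clamped with a warning instead of erroring, because smoothed phantom
   edges legitimately underflow.
4. **Double centering** (`double_center`): subtracting each subject's row
   mean removes $\alpha_s$ *exactly* under the model above; subtracting the
   column means (the stored **group mean profile**, GMP) removes the shared
   $\mu_v$ structure. Both row and column means of the residual are zero to
   numerical precision, and the tests assert this at $10^{-8}$.
5. **PCA + discriminant combination** (`principal_components`,
   `derive_pattern`): principal components of the residual matrix are
   computed by thin SVD; the subject-space route ($SS^\top$) is
   algebraically identical and is used as an independent oracle in the
   tests (agreement to $10^{-8}$). Eigenvector signs are fixed
   deterministically (largest-magnitude loading coefficient positive).

### Component selection and combination

How many components to keep, and how to combine them "to achieve maximum
distinction" between groups, is genuinely open in the field's software
practice. The package's choice: take the smallest prefix of components
whose cumulative variance accounted for reaches 50% (`vaf_cutoff`,
configurable), then combine their subject scores with a Fisher linear
discriminant (pooled within-group covariance, ridge $10^{-8}$ on the
diagonal for numerical safety). The combined voxel map is renormalized to
unit norm and its sign fixed so that patients express the pattern more than
controls. When a single component already explains 50% of the variance the
combination degenerates to that component, which is the common outcome on
strongly patterned data.

### Z convention

Expression scores are Z-transformed as $(\mathrm{raw} - m_c)/s$, with $m_c$
always the control mean. Two conventions for $s$ are implemented:

* `"control"` (default): $s$ = control SD, so control scores have mean 0
  and SD 1 by construction;
* `"pooled"`: $s$ = combined-sample SD. Published control-group expressions
  with SD visibly below 1 suggest some software normalizes by a
  combined-sample spread; offering both makes either reading reproducible.

### Prospective scoring

`tpr_score` centers a new scan's masked log profile by **its own mean**
(the single-subject counterpart of row centering), subtracts the stored
GMP, and takes the inner product with the pattern weights. Because the
centering bookkeeping is identical to derivation, forward-scoring a
derivation subject reproduces its derivation score exactly (tested at
$10^{-10}$; observed agreement is at machine precision). Post-treatment
scans are scored against the fixed baseline pattern and its baseline Z
reference — expression change is meaningful only against a fixed yardstick.
Scores are invariant to multiplying a scan by any positive constant.

## What the synthetic cohort emulates — and what it does not

`make_template` builds a deterministic ellipsoidal "brain" with a
gray-shell/white-core radial profile; `make_planted_pattern` plants a
topography of isotropic Gaussian blobs (truncated at 3 SD), mean-centered
and unit-normalized over the mask — by default bilateral inferior
(cerebellum-like) and central (brainstem/thalamus-like) hypermetabolic
blobs against posterior-superior (parieto-occipital-like) hypometabolic
blobs, echoing the lymphoma-related topography.

`cohort_config` defaults are the study conditions: 49 controls and 64
patients; control expressions $z_s \sim N(0,1)$ and patient expressions
$N(1.3, 0.9^2)$, echoing the observed patient score distribution
(1.28 ± 0.93); `sigma_global = 0.2` (a ±20% scanner/dose scaling, typical
for uncalibrated PET); `sigma_noise = 0.01`, chosen once so the per-voxel
log-domain signal-to-noise ratio (RMS planted signal over noise SD) is
about 0.5 at the default mask size — i.e. the pattern is well below the
voxel noise floor and is recoverable only through its spatial covariance,
which is the point of the method. These are fixture choices, not claims
about patient data.

Deliberately not emulated: anatomy, partial-volume effects, scanner noise
correlation, attenuation or reconstruction artifacts, registration error.
Passing recovery tests therefore demonstrate the *estimator's* correctness
under its own model assumptions, not robustness to real-data violations of
them. One visible consequence: the 10 mm smoothing kernel slightly blurs
the planted blobs, capping weight-map recovery around $|r| \approx 0.95$
while expression-score recovery stays near 1.

The whole-body phantom (`simulate_body_phantom`) paints ellipsoids or boxes
at constant SUV with membership decided by voxel-center inclusion, which
makes ground-truth volumes exact integer counts (the worked fixture — a
10×10×10-voxel box at SUV 10 on 4 mm spacing — has TMTV exactly 64 mL and
TLG exactly 640). Overlapping solids are rejected so truth labels stay
unambiguous.

## Lesion segmentation and burden metrics

`detect_peaks` finds 26-neighborhood local maxima with SUV ≥ 2.5 outside a
user-supplied exclusion mask (brain, myocardium, bladder, kidney — organs
with high physiological uptake). Flat-topped phantom lesions form plateaus
of tied maxima; each connected plateau is one peak, represented by its
first voxel in the fixed ordering. Automatic peak seeding replaces the
manual seeding of clinical workflows for reproducibility; explicit seeds
can be passed to `segment_all` to mimic the semi-automatic workflow, and
exclusion masks are applied exactly as given (so focal uptake in bone
marrow, spleen or liver is kept unless the user masks it).

`segment_lesion` grows the 26-connected component of voxels at or above
41% of the peak SUV (`fraction = 0.41`, configurable). When two isocontour
regions touch, `segment_all` merges them into one lesion reported under the
higher peak; labels are deterministic (decreasing peak SUV, then voxel
order). TMTV sums lesion voxel volumes; TLG = TMTV × lesion SUVmean; both
identities are enforced to $10^{-9}$ relative in tests, and TMTV is
non-increasing in the isocontour fraction. Base-10 logs are reported as
missing (never $-\infty$) when no lesion is found. For total brain
glycolysis the "total brain metabolic volume" is the full brain-mask volume
by default — the historical threshold-based definition is not pinned down
in accessible sources — with an optional SUV threshold exposed.

## Statistical battery

The study-style "as appropriate" test selection is made explicit and
reproducible: Shapiro–Wilk on each group plus Levene's test (mean-centered,
via `car::leveneTest`) at $\alpha = 0.05$ gate the parametric route
(pooled-variance t, or one-way ANOVA with Bonferroni pairwise t) versus the
rank route (Mann–Whitney, or Kruskal–Wallis with Dunn's pairwise z,
Bonferroni-adjusted over the three pairs). Forced modes reproduce either
branch exactly. The Mann–Whitney test is exact for combined $n \le 20$
without ties; otherwise the tie-corrected normal approximation with
continuity correction is used (the corrected approximation agrees with the
exact test within 0.01 at $n = 10+10$; without the correction the
discrepancy can triple). Pearson χ² on 2×2 tables deliberately omits the
Yates continuity correction — that convention is what reproduces the
published demographic statistics to three decimals. Steiger's Z for two
dependent correlations sharing a variable uses Fisher's transform with the
pooled-correlation covariance term; its null calibration (rejection rate
0.05 ± 0.015 over $10^4$ trivariate-normal draws) is part of the test
suite.

## Numerical and reproducibility conventions

* Fixed column-major voxel linearization everywhere; patterns store a mask
  fingerprint and scoring refuses a mismatch instead of resampling.
* Deterministic eigenvector signs; deterministic lesion labels and peak
  tie-breaks; all cohort randomness flows from one integer seed, giving
  bitwise-identical volumes and pipeline artifacts per seed (pattern
  sidecars and score/burden/stats files contain no timestamps).
* Degenerate inputs error early with specific messages: empty masks,
  non-positive masked means, all-zero residuals, singular within-group
  covariance, unpaired subject ids, invalid correlation triples.

## Problem sizes

Unit tests run on a 24×24×20 grid at 3 mm spacing (≈4,600 mask voxels) with
12 + 15 subjects, small enough to iterate quickly; the end-to-end recovery
checks run the full study conditions (64×64×48 at 2 mm, ≈61,000 template
mask voxels, 49 + 64 subjects) for 10 seeds, and the Monte-Carlo
calibrations use $10^4$ replicates. These sizes were chosen as the smallest
at which each property is meaningfully exercised.

## Known limitations

* Inputs must be co-registered; no spatial normalization, motion or
  partial-volume correction is provided or planned.
* SUV calibration from DICOM metadata is out of scope; SUV volumes are
  taken as given.
* The automatic peak seeding is a stand-in for manual VOI editing; on real
  whole-body data it will propose peaks a physician would reject (use
  `seeds =` and exclusion masks to reproduce a manual workflow).
* Bootstrap reliability maps, permutation p-values for pattern expression,
  and survival analysis are out of scope.
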