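Package: covpet
Title: Metabolic Covariance Pattern Analysis and Tumor Burden Metrics for FDG-PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives disease-related metabolic brain covariance patterns from
    FDG-PET cohorts with the scaled subprofile model of principal component
    analysis (SSM-PCA): Gaussian smoothing, whole-brain intensity
    normalization, log transform, double-centering, principal components and
    a Fisher-discriminant combination, with prospective single-scan
    topographic profile rating (Z-scored pattern expression). Also segments
    FDG-avid lesions on whole-body SUV volumes at a percentage-of-SUVmax
    isocontour and computes metabolic tumor volume (TMTV), total lesion
    glycolysis (TLG) and total brain glycolysis (TBG), and provides the
    accompanying statistical battery (gated two-sample and three-group
    comparisons, Pearson chi-square, correlations, and Steiger's test for
    dependent correlation coefficients). A synthetic-cohort generator with a
    planted covariance pattern and lesion phantoms makes every stage testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    car,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
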