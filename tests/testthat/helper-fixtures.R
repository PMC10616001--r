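# Small, fast fixtures shared across test files. Everything is generated in
# code; the geometry is deliberately tiny (a 24^3 grid at 3 mm) so unit
# tests stay quick while the full-size study conditions are exercised in the
# dedicated end-to-end tests.

small_template <- function() make_template(c(24, 24, 20), c(3, 3, 3))

# Two-blob pattern (one hyper-, one hypometabolic) with centers placed well
# inside the small template's brain mask.
small_pattern_spec <- function(template) {
  # centers snapped to voxel centers so field extrema are unambiguous
  vox_center <- function(i) (i - 0.5) * template$spacing_mm
  rad <- 0.10 * mean(template$grid_shape * template$spacing_mm)
  list(
    pattern_blob(vox_center(c(10, 10, 9)), rad, +1, 1),
    pattern_blob(vox_center(c(15, 14, 12)), rad, -1, 1)
  )
}

small_cohort <- function(seed = 1, n_control = 12, n_patient = 15,
                         sigma_noise = 0.01) {
  tpl <- small_template()
  pat <- make_planted_pattern(tpl, small_pattern_spec(tpl))
  simulate_cohort(tpl, pat,
                  cohort_config(n_control = n_control, n_patient = n_patient,
                                sigma_noise = sigma_noise, seed = seed))
}

# Derivation on the small cohort, memoised so several test files can share
# one derivation without re-paying the cost.
small_derivation <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- small_cohort()
      d <- derive_covariance_pattern(co$scans, co$labels, fwhm_mm = 8)
      cache <<- list(cohort = co, derived = d)
    }
    cache
  }
})

# Whole-body phantom with the worked box lesion: 10x10x10 voxels at SUV 10
# on background 0.5, 4 mm spacing. The box center sits on the voxel-corner
# lattice so the ground-truth count is exactly 1000.
box_phantom <- function() {
  simulate_body_phantom(body_phantom_spec(
    grid_shape = c(24, 24, 24), spacing_mm = c(4, 4, 4),
    background_suv = 0.5,
    lesions = list(phantom_solid(c(48, 48, 48), c(20, 20, 20), suv = 10,
                                 shape = "box"))
  ))
}
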