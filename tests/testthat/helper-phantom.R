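# Shared fixtures: small grids keep unit tests fast; physical anatomy
# (in mm) is identical to the default spec, only the sampling is
# coarser.

small_spec <- function(...) {
  phantom_spec(shape = c(48, 48, 48), spacing = c(0.5, 0.5, 0.5), ...)
}

# All scanner degradation and biological jitter switched off: volumes
# are piecewise-constant and the chain should be exact.
exact_spec <- function(...) {
  small_spec(ct_fwhm_mm = 0, pet_fwhm_mm = 0, ct_noise_sd = 0,
             pet_noise_cv = 0, hu_sd_body = 0, hu_sd_lung = 0,
             hu_sd_lesion = 0, animal_uptake_cv = 0, scan_cv = 0,
             baseline_jitter_cv = 0, ...)
}

# Realistic PSF but no noise: segmentation should be near-exact.
noiseless_spec <- function(...) {
  small_spec(ct_noise_sd = 0, pet_noise_cv = 0, hu_sd_body = 0,
             hu_sd_lung = 0, hu_sd_lesion = 0, ...)
}

background_mask_for <- function(spec) {
  an <- fibroPET:::phantom_anatomy(spec)
  bg <- array(FALSE, an$dims)
  bg[an$bg_idx] <- TRUE
  bg
}

truth_lung_mask_for <- function(spec) {
  fibroPET:::phantom_anatomy(spec)$lung_mask
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# A metadata row for hand-built PET volumes: acquisition at injection
# time, so decay correction is the identity.
simple_meta <- function(dose = 5, weight = 20, tracer = "FDG") {
  scan_meta("A1", "NaCl", 0, tracer, dose,
            "2021-03-01T09:00:00", "2021-03-01T09:00:00", weight)
}

# Small demo study shared by the report tests (computed once per run).
.demo_cache <- new.env(parent = emptyenv())
demo_metrics <- function() {
  if (is.null(.demo_cache$metrics)) {
    .demo_cache$metrics <- cohort_metrics(small_spec(), n_per_group = 2, seed = 11)
  }
  .demo_cache$metrics
}
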