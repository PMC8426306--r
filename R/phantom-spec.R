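## PhantomSpec: all tunable parameters of the synthetic bleomycin study.
## Anatomy is fixed in millimetres; the grid only changes sampling.

STUDY_GROUPS <- c("NaCl", "BLM", "BLM+pirfenidone", "BLM+nintedanib")
TRACERS <- c("FDG", "FMISO")
F18_HALF_LIFE_MIN <- 109.77

## Imaging sessions: CT and FMISO on the nominal day, FDG the day
## before (tracers are interleaved on consecutive days); day 0 is the
## common baseline.
SESSION_DAYS <- c(0, 9, 16, 23)
fdg_day <- function(session) ifelse(session == 0, 0, session - 1)

#' Parameters of the synthetic bleomycin mouse-thorax study
#'
#' Returns the parameter set driving the digital phantom: grid geometry,
#' tissue densities, disease and therapy dynamics, tracer uptake model,
#' scanner degradation (PSF + noise) and the random seed. Defaults are
#' calibrated so that the ground-truth group contrasts match the
#' headline effect sizes of the bleomycin model at established fibrosis
#' (day 22/23): BLM/NaCl of 1.4 on mean lung density (HU + 1000 scale),
#' 2.6 on lung FDG %ID/g and 3.2 on lung FMISO %ID/g; vehicle/treated of
#' 1.2 / 2.9 / 2.6 (pirfenidone) and 1.2 / 2.3 / 2.5 (nintedanib).
#'
#' @param shape Grid size in voxels (length 3).
#' @param spacing Voxel spacing in mm (length 3 or scalar).
#' @param body_semiaxes_mm,lung_semiaxes_mm,lung_offset_mm Ellipsoid
#'   anatomy: thorax body, each lung field, and the lateral displacement
#'   of the lung centres from the body centre.
#' @param bg_roi Background reference region (paraspinal soft tissue):
#'   cylinder centre (mm, relative to body centre), radius and
#'   half-length in mm.
#' @param hu_body,hu_lung,hu_lesion Mean Hounsfield units per tissue.
#' @param hu_sd_body,hu_sd_lung,hu_sd_lesion Pre-blur HU texture SD.
#' @param ct_fwhm_mm,pet_fwhm_mm Point-spread FWHM per modality.
#' @param ct_noise_sd Additive post-blur CT noise SD (HU).
#' @param pet_noise_cv Multiplicative PET acquisition noise (coefficient
#'   of variation), applied before the reconstruction point-spread,
#'   which smooths it spatially.
#' @param onset_day,peak_day,peak_burden Disease trajectory: lesion
#'   volume fraction of the lung ramps linearly from `onset_day` to
#'   `peak_burden` at `peak_day`, then plateaus.
#' @param aggressiveness_sd,aggressiveness_range Per-animal growth
#'   multiplier: truncated normal around 1.
#' @param baseline_jitter_cv Lognormal CV of the pre-treatment (day <= 9)
#'   burden, independent of aggressiveness.
#' @param therapy Per-arm effect list. `growth_mult` scales lesion
#'   growth after treatment start (day 9); `fdg_avidity`/`fmiso_avidity`
#'   scale the excess (multiplier - 1) of lesion/halo uptake;
#'   `fdg_background`/`fmiso_background` scale whole-lung background
#'   uptake under treatment.
#' @param background_idg True background-tissue uptake, %ID/g, used for
#'   body, blood and normal lung.
#' @param fdg_lesion_mult,fmiso_lesion_mult Lesion-to-background uptake
#'   multipliers once the tracer's uptake has switched on.
#' @param halo_mult FMISO multiplier of the peri-lesional halo.
#' @param halo_coupling Coupling of halo avidity to the animal's
#'   aggressiveness multiplier `a`: the halo excess is scaled by
#'   `1 + halo_coupling * (a - 1)`.
#' @param fdg_onset_day,fmiso_onset_day First day with elevated tracer
#'   uptake in lesions (and halo, FMISO).
#' @param halo_width_mm Width of the peri-lesional halo shell.
#' @param lesion_margin_mm Lesions are confined to the lung eroded by
#'   this margin so consolidations stay interior to the lung field.
#' @param n_blobs_per_lung Number of lesion seeds per lung.
#' @param blob_frac Range of the radial position of blob centres along
#'   the lung semi-axes (0 = centre, 1 = surface).
#' @param animal_uptake_cv Stable per-animal (and per-tracer) global
#'   uptake multiplier CV: between-animal biological variability, shared
#'   by all of an animal's scans so baseline thresholds cover it.
#' @param scan_cv Day-to-day per-scan multiplier CV on top of the
#'   animal level (residual biological + dose-calibration variability).
#' @param fdg_dose_mbq,fmiso_dose_mbq Injected doses, MBq.
#' @param fdg_uptake_min,fmiso_uptake_min Injection-to-acquisition
#'   delay, minutes.
#' @param weight_g Body weight, g.
#' @param half_life_min Isotope half-life (fluorine-18), minutes.
#' @param seed Base random seed of the study.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96, 96, 96),
                         spacing = c(0.25, 0.25, 0.25),
                         body_semiaxes_mm = c(11, 10, 11.5),
                         lung_semiaxes_mm = c(3.8, 5, 7),
                         lung_offset_mm = 5,
                         bg_roi = list(center = c(0, 7.5, 0), radius = 1.2, halflen = 5),
                         hu_body = 40, hu_lung = -600, hu_lesion = -30,
                         hu_sd_body = 15, hu_sd_lung = 50, hu_sd_lesion = 60,
                         ct_fwhm_mm = 0.4, pet_fwhm_mm = 1.2,
                         ct_noise_sd = 30, pet_noise_cv = 0.05,
                         onset_day = 7, peak_day = 16, peak_burden = 0.28,
                         aggressiveness_sd = 0.25,
                         aggressiveness_range = c(0.3, 2),
                         baseline_jitter_cv = 0.05,
                         therapy = list(
                           pirfenidone = list(growth_mult = 0.25,
                                              fdg_avidity = 0, fdg_background = 0.8966,
                                              fmiso_avidity = 0.2298, fmiso_background = 1),
                           nintedanib = list(growth_mult = 0.25,
                                             fdg_avidity = 0.1958, fdg_background = 1,
                                             fmiso_avidity = 0.2788, fmiso_background = 1)),
                         background_idg = 1.0,
                         fdg_lesion_mult = 6.7123,
                         fmiso_lesion_mult = 8.4024,
                         halo_mult = 3.0,
                         halo_coupling = 1,
                         fdg_onset_day = 15, fmiso_onset_day = 9,
                         halo_width_mm = 0.5,
                         lesion_margin_mm = 1.0,
                         n_blobs_per_lung = 2,
                         blob_frac = c(0.35, 0.6),
                         animal_uptake_cv = 0.055,
                         scan_cv = 0.02,
                         fdg_dose_mbq = 5, fmiso_dose_mbq = 10,
                         fdg_uptake_min = 20, fmiso_uptake_min = 120,
                         weight_g = 20,
                         half_life_min = F18_HALF_LIFE_MIN,
                         seed = 1) {
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  spec <- list(
    shape = as.integer(shape), spacing = spacing,
    body_semiaxes_mm = body_semiaxes_mm, lung_semiaxes_mm = lung_semiaxes_mm,
    lung_offset_mm = lung_offset_mm, bg_roi = bg_roi,
    hu_body = hu_body, hu_lung = hu_lung, hu_lesion = hu_lesion,
    hu_sd_body = hu_sd_body, hu_sd_lung = hu_sd_lung, hu_sd_lesion = hu_sd_lesion,
    ct_fwhm_mm = ct_fwhm_mm, pet_fwhm_mm = pet_fwhm_mm,
    ct_noise_sd = ct_noise_sd, pet_noise_cv = pet_noise_cv,
    onset_day = onset_day, peak_day = peak_day, peak_burden = peak_burden,
    aggressiveness_sd = aggressiveness_sd,
    aggressiveness_range = aggressiveness_range,
    baseline_jitter_cv = baseline_jitter_cv,
    therapy = therapy,
    background_idg = background_idg,
    fdg_lesion_mult = fdg_lesion_mult, fmiso_lesion_mult = fmiso_lesion_mult,
    halo_mult = halo_mult, halo_coupling = halo_coupling,
    fdg_onset_day = fdg_onset_day, fmiso_onset_day = fmiso_onset_day,
    halo_width_mm = halo_width_mm, lesion_margin_mm = lesion_margin_mm,
    n_blobs_per_lung = as.integer(n_blobs_per_lung), blob_frac = blob_frac,
    animal_uptake_cv = animal_uptake_cv, scan_cv = scan_cv,
    fdg_dose_mbq = fdg_dose_mbq, fmiso_dose_mbq = fmiso_dose_mbq,
    fdg_uptake_min = fdg_uptake_min, fmiso_uptake_min = fmiso_uptake_min,
    weight_g = weight_g, half_life_min = half_life_min,
    seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (length(shape) != 3 || any(shape < 8)) stop("grid shape must be 3 axes of >= 8 voxels")
    if (any(spacing <= 0)) stop("voxel spacing must be > 0")
    if (any(c(hu_sd_body, hu_sd_lung, hu_sd_lesion, ct_noise_sd) < 0) ||
        pet_noise_cv < 0 || scan_cv < 0 || animal_uptake_cv < 0 ||
        baseline_jitter_cv < 0 || aggressiveness_sd < 0)
      stop("all variances must be >= 0")
    if (peak_burden < 0 || peak_burden > 1) stop("peak_burden must be in [0, 1]")
    for (nm in names(therapy)) {
      gm <- therapy[[nm]]$growth_mult
      if (is.null(gm) || gm < 0 || gm > 1)
        stop("therapy growth multiplier must be in [0, 1] (arm '", nm, "')")
    }
    for (d in c(onset_day, peak_day, fdg_onset_day, fmiso_onset_day))
      if (d < 0 || d > 23) stop("onset/peak days must lie in the study window [0, 23]")
    if (onset_day >= peak_day) stop("onset_day must precede peak_day")
    if (fdg_dose_mbq <= 0 || fmiso_dose_mbq <= 0) stop("injected doses must be > 0")
    if (weight_g <= 0) stop("body weight must be > 0")
    if (half_life_min <= 0) stop("half-life must be > 0")
    ## anatomy must fit in the grid with an air margin, in mm
    fov <- shape * spacing
    if (any(2 * body_semiaxes_mm + 1 > fov))
      stop("grid too small: thorax does not fit in the field of view")
    ext <- lung_offset_mm + lung_semiaxes_mm[1]
    if (2 * ext > fov[1] || any(lung_semiaxes_mm < 2 * spacing))
      stop("grid too small to contain two lung fields")
    invisible(NULL)
  })
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %dx%dx%d voxels @ %.3g mm, seed %d\n",
              x$shape[1], x$shape[2], x$shape[3], x$spacing[1], x$seed))
  cat(sprintf("  disease: onset D%g, peak burden %.2f at D%g; arms: %s\n",
              x$onset_day, x$peak_burden, x$peak_day,
              paste(names(x$therapy), collapse = ", ")))
  invisible(x)
}

#' Per-scan acquisition metadata
#'
#' One record per scan: animal, group, study day, tracer, injected dose,
#' injection and acquisition times, body weight and isotope half-life.
#' CT rows carry `tracer = "CT"` and no dose.
#'
#' @param animal_id,group,day,tracer,dose_mbq,t_injection,t_scan,weight_g,half_life_min
#'   Field values; times are ISO 8601 strings.
#' @param file Optional volume file name.
#' @return A one-row data frame.
#' @export
scan_meta <- function(animal_id, group, day, tracer, dose_mbq,
                      t_injection, t_scan, weight_g,
                      half_life_min = F18_HALF_LIFE_MIN, file = NA_character_) {
  if (!group %in% STUDY_GROUPS)
    stop("unknown group '", group, "'; expected one of ",
         paste(STUDY_GROUPS, collapse = ", "))
  if (!tracer %in% c(TRACERS, "CT")) stop("unknown tracer '", tracer, "'")
  if (tracer != "CT") {
    if (!is.finite(dose_mbq) || dose_mbq <= 0) stop("injected dose must be > 0")
    if (parse_iso8601(t_scan) < parse_iso8601(t_injection))
      stop("acquisition time precedes injection time")
  }
  if (!is.finite(weight_g) || weight_g <= 0) stop("body weight must be > 0")
  data.frame(animal_id = animal_id, group = group, day = as.integer(day),
             session = as.integer(if (tracer == "FDG" && day > 0) day + 1 else day),
             tracer = tracer, dose_MBq = dose_mbq,
             t_injection = t_injection, t_scan = t_scan,
             weight_g = weight_g, half_life_min = half_life_min,
             file = file, stringsAsFactors = FALSE)
}

## ISO 8601 (or space-separated) timestamp to POSIXct, UTC.
parse_iso8601 <- function(x) {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  fallback <- is.na(out) & !is.na(x)
  if (any(fallback)) out[fallback] <- as.POSIXct(x[fallback], tz = "UTC")
  out
}

## Minutes elapsed between injection and acquisition for a metadata row.
elapsed_minutes <- function(meta) {
  as.numeric(difftime(parse_iso8601(meta$t_scan), parse_iso8601(meta$t_injection),
                      units = "mins"))
}
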