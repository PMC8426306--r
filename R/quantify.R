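## PET quantification: decay correction, %ID/g, SUV, LTBR, MLV, HLV and
## density-gated uptake. All metrics assume a soft-tissue density of
## 1 g/mL, so 1 mL of tissue weighs 1 g.

#' Decay-correct an activity to the injection reference time
#'
#' Activity measured `elapsed_min` minutes after the reference time is
#' scaled back by `2^(elapsed / half_life)`.
#'
#' @param activity Measured activity (any unit; vectorised).
#' @param elapsed_min Minutes elapsed since the reference time (>= 0).
#' @param half_life_min Isotope half-life in minutes (> 0).
#' @export
decay_correct <- function(activity, elapsed_min, half_life_min) {
  if (any(half_life_min <= 0)) stop("half-life must be > 0")
  if (any(elapsed_min < 0)) stop("elapsed time must be >= 0")
  activity * 2^(elapsed_min / half_life_min)
}

## Decay-corrected concentration map (kBq/mL at injection time).
corrected_concentration <- function(pet, meta) {
  stopifnot(inherits(pet, "volume_grid"))
  if (pet$modality != "PET") stop("expected a PET volume in kBq/mL")
  decay_correct(pet$data, elapsed_minutes(meta), meta$half_life_min)
}

#' Percent injected dose per gram
#'
#' Converts a PET volume to %ID/g: the decay-corrected activity
#' concentration (MBq/mL, 1 mL = 1 g) as a percentage of the injected
#' dose.
#'
#' @param pet A PET `volume_grid` (kBq/mL at acquisition).
#' @param meta A [scan_meta()] row (dose, times, half-life).
#' @param lung_mask Optional logical mask; when given, `lung_mean` is
#'   the mean %ID/g over it.
#' @return List with `map` (array, %ID/g) and `lung_mean` (or `NA`).
#' @export
percent_id_per_g <- function(pet, meta, lung_mask = NULL) {
  if (!is.finite(meta$dose_MBq) || meta$dose_MBq <= 0)
    stop("injected dose must be > 0")
  conc <- corrected_concentration(pet, meta)         # kBq/mL at injection
  map <- 100 * (conc / 1000) / meta$dose_MBq          # % of dose per g
  list(map = map,
       lung_mean = if (is.null(lung_mask)) NA_real_ else mean(map[lung_mask]))
}

#' Standardized uptake value
#'
#' SUV = decay-corrected concentration / (injected dose / body weight),
#' with tissue density 1 g/mL. Satisfies the identity
#' `SUV = %ID/g * weight_g / 100` voxelwise.
#'
#' @inheritParams percent_id_per_g
#' @return List with `map`, `suv_mean`, `suv_max` (means over
#'   `lung_mask` when given, else whole volume).
#' @export
suv <- function(pet, meta, lung_mask = NULL) {
  if (!is.finite(meta$weight_g) || meta$weight_g <= 0)
    stop("body weight must be > 0")
  if (!is.finite(meta$dose_MBq) || meta$dose_MBq <= 0)
    stop("injected dose must be > 0")
  conc <- corrected_concentration(pet, meta)                 # kBq/mL
  map <- conc / (meta$dose_MBq * 1000 / meta$weight_g)        # kBq/mL / (kBq/g)
  vals <- if (is.null(lung_mask)) map else map[lung_mask]
  list(map = map, suv_mean = mean(vals), suv_max = max(vals))
}

#' Lung-to-background ratio
#'
#' Ratio of lung mean to background-region mean of the same map. Scale
#' invariant: identical on kBq/mL, %ID/g or SUV maps.
#'
#' @param map Numeric array (any uptake scale).
#' @param lung_mask,bg_mask Disjoint logical masks; `bg_mask` non-empty.
#' @export
lung_to_background_ratio <- function(map, lung_mask, bg_mask) {
  if (!any(bg_mask)) stop("background mask is empty")
  if (any(lung_mask & bg_mask)) stop("lung and background masks overlap")
  bg <- mean(map[bg_mask])
  if (bg == 0) stop("background mean is zero")
  mean(map[lung_mask]) / bg
}

#' Baseline threshold for the metabolic lung volume
#'
#' MLV threshold = mean + 2 SD (sample SD) of the per-animal baseline
#' (day 0) SUVmean values.
#'
#' @param baseline_suvmeans Numeric vector, one SUVmean per baseline
#'   animal (length >= 2).
#' @param tracer Tracer label carried along for bookkeeping.
#' @return An `mlv_threshold` list with `threshold`, `baseline_mean`,
#'   `baseline_sd`, `n`, `tracer`.
#' @export
mlv_threshold <- function(baseline_suvmeans, tracer = "FDG") {
  x <- baseline_suvmeans[is.finite(baseline_suvmeans)]
  if (length(x) < 2) stop("need >= 2 baseline scans for the MLV threshold")
  m <- mean(x); s <- sd(x)
  structure(list(threshold = m + 2 * s, baseline_mean = m, baseline_sd = s,
                 n = length(x), tracer = tracer),
            class = "mlv_threshold")
}

#' Metabolic lung volume
#'
#' Volume of lung with SUV strictly above the baseline-derived
#' threshold.
#'
#' @param suv_map SUV array.
#' @param lung_mask Logical mask.
#' @param threshold An [mlv_threshold()] or a number.
#' @param spacing Voxel spacing, mm.
#' @return Data frame with `mlv_ml` and `mlv_pct` (% of lung volume).
#' @export
metabolic_lung_volume <- function(suv_map, lung_mask, threshold, spacing) {
  thr <- if (inherits(threshold, "mlv_threshold")) threshold$threshold else threshold
  n_hot <- sum(suv_map[lung_mask] > thr)
  n <- sum(lung_mask)
  data.frame(mlv_ml = n_hot * voxel_volume_ml(spacing),
             mlv_pct = 100 * n_hot / n)
}

#' Hypoxic lung volume
#'
#' FMISO-only: a lung voxel is hypoxic when its voxel-to-background
#' ratio is at least `multiplier` (default 1.4).
#'
#' @param map Uptake array (any common scale; the ratio cancels it).
#' @param lung_mask,bg_mask Disjoint logical masks.
#' @param multiplier Ratio threshold.
#' @param tracer Must be `"FMISO"`; HLV is not defined for FDG.
#' @param spacing Voxel spacing in mm (for the volume in mL).
#' @return Data frame with `hlv_ml` and `hlv_pct` (% of lung volume).
#' @export
hypoxic_lung_volume <- function(map, lung_mask, bg_mask, multiplier = 1.4,
                                tracer = "FMISO", spacing = c(1, 1, 1)) {
  if (!identical(tracer, "FMISO"))
    stop("the hypoxic lung volume is defined only for FMISO scans")
  if (!any(bg_mask)) stop("background mask is empty")
  bg <- mean(map[bg_mask])
  if (bg <= 0) stop("background mean must be > 0")
  n_hot <- sum(map[lung_mask] >= multiplier * bg)
  n <- sum(lung_mask)
  data.frame(hlv_ml = n_hot * voxel_volume_ml(spacing),
             hlv_pct = 100 * n_hot / n)
}

#' Density-gated uptake
#'
#' Mean %ID/g separately over the aerated and high-density lung classes
#' of a CT partition. An absent class yields `NA` (flagged missing, not
#' zero).
#'
#' @param idg_map %ID/g array co-registered with the partition.
#' @param partition A `lung_partition`.
#' @return Data frame with `aerated_idg` and `high_density_idg`.
#' @export
density_gated_uptake <- function(idg_map, partition) {
  stopifnot(inherits(partition, "lung_partition"))
  if (!identical(dim(idg_map), dim(partition$class)))
    stop("uptake map and partition are on different grids")
  cls <- partition$class
  one <- function(k) if (any(cls == k)) mean(idg_map[cls == k]) else NA_real_
  data.frame(aerated_idg = one(1L), high_density_idg = one(2L))
}

#' Quantify one imaging session
#'
#' Runs the full per-session chain on in-memory volumes: lung
#' segmentation and CT metrics from the CT, then per-tracer %ID/g, SUV,
#' LTBR, HLV (FMISO) and density-gated uptake.
#'
#' @param ct CT `volume_grid`.
#' @param pet_list Named list of PET `volume_grid`s (names are tracers).
#' @param meta Metadata rows covering the PET scans (and optionally CT).
#' @param bg_mask Background-region logical mask for LTBR/HLV.
#' @param config A [pipeline_config()].
#' @return Data frame, one row per scan (CT row first when present).
#' @export
quantify_session <- function(ct, pet_list, meta, bg_mask,
                             config = pipeline_config()) {
  mask <- extract_lung_mask(ct, config$seg)
  part <- partition_density(ct, mask, config$bands)
  ctm <- ct_metrics(ct, part)
  ct_meta <- meta[meta$tracer == "CT", , drop = FALSE]
  base <- meta[meta$tracer != "CT", , drop = FALSE][1, c("animal_id", "group"), drop = FALSE]
  rows <- list(data.frame(
    animal_id = base$animal_id, group = base$group,
    day = if (nrow(ct_meta)) ct_meta$day else meta$session[1],
    session = meta$session[1], tracer = "CT",
    mld_hu = ctm$mld_hu, aerated_pct = ctm$aerated_pct,
    lung_volume_ml = ctm$lung_volume_ml,
    lung_idg = NA_real_, suv_mean = NA_real_, suv_max = NA_real_,
    ltbr = NA_real_, hlv_pct = NA_real_,
    aerated_idg = NA_real_, high_density_idg = NA_real_))
  for (tr in names(pet_list)) {
    m <- meta[meta$tracer == tr, , drop = FALSE]
    if (nrow(m) != 1) stop("metadata row missing for tracer ", tr)
    pid <- percent_id_per_g(pet_list[[tr]], m, mask)
    sv <- suv(pet_list[[tr]], m, mask)
    ltbr <- lung_to_background_ratio(pid$map, mask, bg_mask)
    hlv <- if (tr == "FMISO")
      hypoxic_lung_volume(pid$map, mask, bg_mask, config$hlv_multiplier, tr,
                          ct$spacing)$hlv_pct
    else NA_real_
    gated <- density_gated_uptake(pid$map, part)
    rows[[length(rows) + 1L]] <- data.frame(
      animal_id = m$animal_id, group = m$group, day = m$day,
      session = m$session, tracer = tr,
      mld_hu = ctm$mld_hu, aerated_pct = ctm$aerated_pct,
      lung_volume_ml = ctm$lung_volume_ml,
      lung_idg = pid$lung_mean, suv_mean = sv$suv_mean, suv_max = sv$suv_max,
      ltbr = ltbr, hlv_pct = hlv,
      aerated_idg = gated$aerated_idg, high_density_idg = gated$high_density_idg)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Quantify a file-based study
#'
#' Reads every session of a study table (see [load_study()]), segments
#' each CT, quantifies each PET scan, and appends the baseline-derived
#' metabolic lung volume per FDG scan.
#'
#' @param study A study table from [load_study()] or [generate_cohort()].
#' @param root Directory containing the volume files.
#' @param config A [pipeline_config()].
#' @param bg_mask Background logical mask; default reads
#'   `truth/background_roi.nii.gz` under `root`.
#' @return Per-scan metrics data frame; MLV thresholds are attached as
#'   attribute `mlv_thresholds`.
#' @export
quantify_study <- function(study, root, config = pipeline_config(),
                           bg_mask = NULL) {
  if (is.null(bg_mask)) {
    f <- file.path(root, "truth", "background_roi.nii.gz")
    if (!file.exists(f))
      stop("no background mask: pass `bg_mask` or provide ", f)
    bg_mask <- read_labels(f) > 0
  }
  keys <- unique(study[, c("animal_id", "session")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- study$animal_id == keys$animal_id[i] & study$session == keys$session[i]
    meta <- study[sel, , drop = FALSE]
    ct_row <- meta[meta$tracer == "CT", , drop = FALSE]
    if (nrow(ct_row) == 0) stop("session without CT: ", keys$animal_id[i],
                                " day ", keys$session[i])
    ct <- read_volume(file.path(root, ct_row$file))
    pets <- list()
    for (tr in meta$tracer[meta$tracer != "CT"])
      pets[[tr]] <- read_volume(file.path(root, meta$file[meta$tracer == tr]))
    out[[i]] <- quantify_session(ct, pets, meta, bg_mask, config)
  }
  metrics <- do.call(rbind, out)
  ## baseline MLV thresholds (day-0 SUVmean across animals, per tracer)
  thr <- list()
  for (tr in intersect(unique(metrics$tracer), TRACERS)) {
    base <- metrics$suv_mean[metrics$tracer == tr & metrics$session == 0]
    if (sum(is.finite(base)) >= 2) thr[[tr]] <- mlv_threshold(base, tr)
  }
  if (!is.null(thr$FDG)) {
    metrics$mlv_pct <- NA_real_
    fdg <- which(metrics$tracer == "FDG")
    for (i in fdg) {
      m <- study[study$animal_id == metrics$animal_id[i] &
                   study$tracer == "FDG" & study$day == metrics$day[i], , drop = FALSE]
      pet <- read_volume(file.path(root, m$file[1]))
      ct_row <- study[study$animal_id == metrics$animal_id[i] &
                        study$tracer == "CT" &
                        study$session == metrics$session[i], , drop = FALSE]
      mask <- extract_lung_mask(read_volume(file.path(root, ct_row$file[1])),
                                config$seg)
      sv <- suv(pet, m[1, ], mask)
      metrics$mlv_pct[i] <- metabolic_lung_volume(sv$map, mask, thr$FDG,
                                                  pet$spacing)$mlv_pct
    }
  }
  attr(metrics, "mlv_thresholds") <- thr
  metrics
}
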