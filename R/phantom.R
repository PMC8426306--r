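## Digital mouse-thorax phantom: CT + dual-tracer PET volumes with
## ground truth, emulating a longitudinal bleomycin fibrosis study.
##
## Anatomy is a fixed ellipsoid thorax with two ellipsoid lung fields.
## Disease is a set of Gaussian-seeded spherical consolidations grown
## concentrically inside the lung; a peri-lesional "halo" (aerated on CT
## but hypoxia-tracer avid) covers the lesion shell plus the region the
## lesions will grow into. Volumes are degraded by a separable Gaussian
## PSF and voxel noise.

.anatomy_cache <- new.env(parent = emptyenv())

phantom_anatomy <- function(spec) {
  key <- paste(c(spec$shape, spec$spacing, spec$body_semiaxes_mm,
                 spec$lung_semiaxes_mm, spec$lung_offset_mm,
                 unlist(spec$bg_roi), spec$lesion_margin_mm), collapse = "|")
  if (!is.null(.anatomy_cache[[key]])) return(.anatomy_cache[[key]])
  dm <- spec$shape
  ax <- lapply(1:3, function(i) (seq_len(dm[i]) - (dm[i] + 1) / 2) * spec$spacing[i])
  ell <- function(center, semi) {
    e1 <- ((ax[[1]] - center[1]) / semi[1])^2
    e2 <- ((ax[[2]] - center[2]) / semi[2])^2
    e3 <- ((ax[[3]] - center[3]) / semi[3])^2
    outer(outer(e1, e2, "+"), e3, "+") <= 1
  }
  body <- ell(c(0, 0, 0), spec$body_semiaxes_mm)
  centers <- list(c(-spec$lung_offset_mm, 0, 0), c(spec$lung_offset_mm, 0, 0))
  lungL <- ell(centers[[1]], spec$lung_semiaxes_mm)
  lungR <- ell(centers[[2]], spec$lung_semiaxes_mm)
  lung <- lungL | lungR
  inner_semi <- pmax(spec$lung_semiaxes_mm - spec$lesion_margin_mm, spec$spacing)
  region <- ell(centers[[1]], inner_semi) | ell(centers[[2]], inner_semi)
  roi <- spec$bg_roi
  r1 <- (ax[[1]] - roi$center[1])^2
  r2 <- (ax[[2]] - roi$center[2])^2
  rz <- abs(ax[[3]] - roi$center[3]) <= roi$halflen
  bg <- outer(outer(r1, r2, "+") <= roi$radius^2, rz, "&") & body & !lung
  lung_idx <- which(lung)
  ijk <- arrayInd(lung_idx, dm)
  coords <- cbind(ax[[1]][ijk[, 1]], ax[[2]][ijk[, 2]], ax[[3]][ijk[, 3]])
  out <- list(dims = dm, nvox = prod(dm),
              body_idx = which(body), lung_idx = lung_idx,
              bg_idx = which(bg), region_sub = region[lung_idx],
              lung_coords = coords, lung_centers = centers,
              lung_mask = lung, n_lung = length(lung_idx))
  .anatomy_cache[[key]] <- out
  out
}

## Deterministic burden trajectory (lesion volume fraction of the lung).
## `e` jitters the pre-treatment level, `a` the post-day-9 growth,
## `growth_mult` is the therapy effect (applies after day 9).
burden_at <- function(day, spec, e = 1, a = 1, growth_mult = 1) {
  base <- function(d) spec$peak_burden *
    pmin(pmax((d - spec$onset_day) / (spec$peak_day - spec$onset_day), 0), 1)
  ifelse(day <= 9,
         e * base(day),
         e * base(9) + a * growth_mult * (base(day) - base(9)))
}

group_growth_mult <- function(group, spec) {
  switch(group,
         "NaCl" = 0,
         "BLM" = 1,
         "BLM+pirfenidone" = spec$therapy$pirfenidone$growth_mult,
         "BLM+nintedanib" = spec$therapy$nintedanib$growth_mult,
         stop("unknown group '", group, "'; expected one of ",
              paste(STUDY_GROUPS, collapse = ", ")))
}

group_arm <- function(group) {
  if (group == "BLM+pirfenidone") "pirfenidone"
  else if (group == "BLM+nintedanib") "nintedanib"
  else NA_character_
}

#' Ground-truth disease trajectory
#'
#' Lesion volume fraction of the lung for a typical (multiplier 1)
#' animal of the given group: zero for controls, a linear ramp from
#' disease onset to the day-16 peak for bleomycin, with therapy arms
#' growing at a reduced rate from treatment start (day 9).
#'
#' @param group One of `"NaCl"`, `"BLM"`, `"BLM+pirfenidone"`,
#'   `"BLM+nintedanib"`.
#' @param day Study day in `[0, 23]` (vectorised).
#' @param spec A [phantom_spec()].
#' @return Burden fraction in `[0, 1]`.
#' @export
disease_trajectory <- function(group, day, spec = phantom_spec()) {
  if (any(day < 0 | day > 23)) stop("day must lie in the study window [0, 23]")
  gm <- group_growth_mult(group, spec)  # validates the group
  if (group == "NaCl") return(rep(0, length(day)))
  burden_at(day, spec, growth_mult = gm)
}

## Lesion voxels (logical over the lung voxel list) for a global radius
## scale; d2 is the n_lung x n_blob matrix of squared distances to blob
## centres, u the relative blob radii.
lesion_from_scale <- function(scale, d2, u, region_sub) {
  if (scale <= 0) return(rep(FALSE, nrow(d2)))
  sel <- d2[, 1] <= (scale * u[1])^2
  for (b in seq_along(u)[-1]) sel <- sel | (d2[, b] <= (scale * u[b])^2)
  sel & region_sub
}

## Find the radius scale whose realised lesion volume matches the target
## voxel count (bisection; saturates at the placement region).
solve_lesion_scale <- function(target, d2, u, region_sub, lower = 0) {
  if (target <= 0) return(max(0, lower))
  count <- function(s) sum(lesion_from_scale(s, d2, u, region_sub))
  hi <- max(1, lower)
  while (count(hi) < target && hi < 64) hi <- hi * 2
  if (count(hi) < target) return(hi)  # region saturated
  lo <- lower
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (count(mid) < target) lo <- mid else hi <- mid
  }
  hi
}

## Times for a scan session.
scan_times <- function(day, uptake_min) {
  inj <- as.POSIXct("2021-03-01 09:00:00", tz = "UTC") + day * 86400
  list(inj = format(inj, "%Y-%m-%dT%H:%M:%S"),
       scan = format(inj + uptake_min * 60, "%Y-%m-%dT%H:%M:%S"))
}

tracer_params <- function(spec, tracer) {
  if (tracer == "FDG")
    list(dose = spec$fdg_dose_mbq, uptake = spec$fdg_uptake_min,
         onset = spec$fdg_onset_day, mult = spec$fdg_lesion_mult)
  else
    list(dose = spec$fmiso_dose_mbq, uptake = spec$fmiso_uptake_min,
         onset = spec$fmiso_onset_day, mult = spec$fmiso_lesion_mult)
}

#' Generate one synthetic animal
#'
#' Simulates all requested imaging sessions of one animal: CT volumes,
#' PET volumes per tracer, per-scan metadata and per-session ground
#' truth. With a fixed `animal_seed` the output is bit-identical across
#' runs.
#'
#' Session days follow the study design: CT and FMISO on the nominal
#' days 0/9/16/23, FDG on the preceding day (0/8/15/22).
#'
#' @param spec A [phantom_spec()].
#' @param group Study group.
#' @param animal_id Identifier string.
#' @param animal_seed Integer seed for this animal's random draws.
#' @param sessions Nominal session days to simulate (subset of
#'   `c(0, 9, 16, 23)`).
#' @param tracers Tracers to simulate (subset of `c("FDG", "FMISO")`).
#' @param with_ct Simulate the CT of each session.
#' @return A list with elements `animal_id`, `group`, `aggressiveness`,
#'   `baseline_jitter`, `anatomy`, and `sessions` (one entry per nominal
#'   day with `ct`, `pet`, `meta`, `truth`).
#' @export
generate_animal <- function(spec, group, animal_id = group,
                            animal_seed = spec$seed,
                            sessions = SESSION_DAYS,
                            tracers = TRACERS,
                            with_ct = TRUE) {
  gm <- group_growth_mult(group, spec)  # also validates the group
  arm <- group_arm(group)
  an <- phantom_anatomy(spec)
  stopifnot(all(sessions %in% SESSION_DAYS))
  set.seed(as.integer(animal_seed %% 2147483647))

  ## per-animal biology (drawn once, shared across timepoints)
  a_i <- min(max(rnorm(1, 1, spec$aggressiveness_sd), spec$aggressiveness_range[1]),
             spec$aggressiveness_range[2])
  cv <- spec$baseline_jitter_cv
  e_i <- exp(rnorm(1, 0, cv) - cv^2 / 2)

  ## lesion seeds: n per lung, direction + radial fraction + weight
  nb <- 2L * spec$n_blobs_per_lung
  dirs <- matrix(rnorm(3 * nb), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  fracs <- stats::runif(nb, spec$blob_frac[1], spec$blob_frac[2])
  w <- stats::runif(nb, 0.5, 1)
  u <- w^(1 / 3)
  side <- rep(c(1L, 2L), length.out = nb)
  centers <- t(vapply(seq_len(nb), function(b)
    unlist(an$lung_centers[[side[b]]]) + dirs[b, ] * fracs[b] * spec$lung_semiaxes_mm,
    numeric(3)))

  ## global uptake multipliers: a stable per-animal component (covered
  ## by baseline-anchored thresholds) times day-to-day per-scan noise;
  ## both symmetric truncated normal, fixed draw order over the full
  ## schedule so they do not depend on the requested subset
  tnorm <- function(n, cv) 1 + pmin(pmax(rnorm(n, 0, cv), -3 * cv), 3 * cv)
  u_animal <- stats::setNames(tnorm(2, spec$animal_uptake_cv), TRACERS)
  s_tab <- matrix(tnorm(length(SESSION_DAYS) * 2, spec$scan_cv),
                  nrow = length(SESSION_DAYS),
                  dimnames = list(as.character(SESSION_DAYS), TRACERS))
  s_tab <- sweep(s_tab, 2, u_animal, "*")

  ## squared distances from lung voxels to blob centres
  d2 <- vapply(seq_len(nb), function(b)
    (an$lung_coords[, 1] - centers[b, 1])^2 +
    (an$lung_coords[, 2] - centers[b, 2])^2 +
    (an$lung_coords[, 3] - centers[b, 3])^2, numeric(an$n_lung))

  ## lesion scale per needed day (monotone growth), plus end of study
  need_days <- sort(unique(c(
    if (with_ct || "FMISO" %in% tracers) sessions,
    if ("FDG" %in% tracers) fdg_day(sessions), 23)))
  scales <- numeric(length(need_days)); names(scales) <- as.character(need_days)
  prev <- 0
  for (d in need_days) {
    b_d <- if (group == "NaCl") 0 else burden_at(d, spec, e_i, a_i, gm)
    prev <- solve_lesion_scale(round(b_d * an$n_lung), d2, u, an$region_sub, prev)
    scales[as.character(d)] <- prev
  }
  lesion_sub_at <- function(d) lesion_from_scale(scales[as.character(d)], d2, u,
                                                 an$region_sub)
  final_sub <- lesion_sub_at(23)
  halo_sub_at <- function(d, lesion_sub) {
    if (d < spec$fmiso_onset_day) return(rep(FALSE, an$n_lung))
    s <- scales[as.character(d)]
    if (s <= 0) return(final_sub & an$region_sub & !lesion_sub)  # no lesion, no shell
    shell <- d2[, 1] <= (s * u[1] + spec$halo_width_mm)^2
    for (b in seq_along(u)[-1]) shell <- shell | (d2[, b] <= (s * u[b] + spec$halo_width_mm)^2)
    ## confined, like the lesions, to the interior placement region so
    ## halo activity sits well inside the lung field
    (final_sub | shell) & an$region_sub & !lesion_sub
  }

  nvox <- an$nvox
  u_bg <- spec$background_idg

  make_ct <- function(lesion_idx) {
    hu <- rep(-1000, nvox); sdv <- rep(0, nvox)
    hu[an$body_idx] <- spec$hu_body;  sdv[an$body_idx] <- spec$hu_sd_body
    hu[an$lung_idx] <- spec$hu_lung;  sdv[an$lung_idx] <- spec$hu_sd_lung
    hu[lesion_idx] <- spec$hu_lesion; sdv[lesion_idx] <- spec$hu_sd_lesion
    hu <- hu + rnorm(nvox) * sdv
    vol <- blur_volume(array(hu, an$dims), spec$ct_fwhm_mm, spec$spacing)
    if (spec$ct_noise_sd > 0) vol <- vol + array(rnorm(nvox, 0, spec$ct_noise_sd), an$dims)
    volume_grid(vol, spec$spacing, "CT")
  }

  ## class-level true %ID/g for one scan
  true_classes <- function(tracer, day, s) {
    tp <- tracer_params(spec, tracer)
    treated <- !is.na(arm) && day > 9
    bgfac <- 1; avid <- 1
    if (treated) {
      th <- spec$therapy[[arm]]
      bgfac <- if (tracer == "FDG") th$fdg_background else th$fmiso_background
      avid <- if (tracer == "FDG") th$fdg_avidity else th$fmiso_avidity
    }
    lesion_on <- day >= tp$onset
    m_les <- if (lesion_on) 1 + (tp$mult - 1) * (if (treated) avid else 1) else 1
    m_halo <- 1
    if (tracer == "FMISO" && day >= spec$fmiso_onset_day) {
      base_ex <- (spec$halo_mult - 1) * (1 + spec$halo_coupling * (a_i - 1))
      m_halo <- 1 + base_ex * (if (treated) avid else 1)
    }
    list(aerated = u_bg * bgfac * s,
         lesion = u_bg * bgfac * m_les * s,
         halo = u_bg * bgfac * m_halo * s,
         blood = u_bg * s, dose = tp$dose, uptake = tp$uptake)
  }

  make_pet <- function(tracer, day, lesion_idx, halo_idx, s) {
    cls <- true_classes(tracer, day, s)
    idg <- rep(0, nvox)
    idg[an$body_idx] <- cls$blood
    idg[an$lung_idx] <- cls$aerated
    idg[halo_idx] <- cls$halo
    idg[lesion_idx] <- cls$lesion
    conc <- array(idg * cls$dose * 10, an$dims)  # kBq/mL at injection reference
    ## acquisition noise enters before the reconstruction point-spread,
    ## which smooths it spatially (as in reconstructed PET)
    if (spec$pet_noise_cv > 0)
      conc <- conc * (1 + array(rnorm(nvox, 0, spec$pet_noise_cv), an$dims))
    conc <- blur_volume(conc, spec$pet_fwhm_mm, spec$spacing)
    conc <- conc * 2^(-cls$uptake / spec$half_life_min)  # decays until acquisition
    volume_grid(conc, spec$spacing, "PET")
  }

  out_sessions <- list()
  for (ses in sessions) {
    les_sub <- lesion_sub_at(ses)
    halo_sub <- halo_sub_at(ses, les_sub)
    lesion_idx <- an$lung_idx[les_sub]
    halo_idx <- an$lung_idx[halo_sub]
    tm <- scan_times(ses, spec$fmiso_uptake_min)
    entry <- list(session = ses, ct = NULL, pet = list(), meta = NULL)
    meta <- list()
    if (with_ct) {
      entry$ct <- make_ct(lesion_idx)
      meta$CT <- scan_meta(animal_id, group, ses, "CT", NA_real_,
                           tm$scan, tm$scan, spec$weight_g, spec$half_life_min)
    }
    truth_cls <- list()
    for (tr in tracers) {
      d_tr <- if (tr == "FDG") fdg_day(ses) else ses
      s <- s_tab[as.character(ses), tr]
      if (tr == "FDG" && d_tr != ses) {
        les_sub_tr <- lesion_sub_at(d_tr)
        lesion_idx_tr <- an$lung_idx[les_sub_tr]
        halo_idx_tr <- integer(0)
        n_les_tr <- sum(les_sub_tr); n_halo_tr <- 0L
      } else {
        lesion_idx_tr <- lesion_idx
        halo_idx_tr <- if (tr == "FMISO") halo_idx else integer(0)
        n_les_tr <- length(lesion_idx); n_halo_tr <- length(halo_idx_tr)
      }
      entry$pet[[tr]] <- make_pet(tr, d_tr, lesion_idx_tr, halo_idx_tr, s)
      tp <- tracer_params(spec, tr)
      tt <- scan_times(d_tr, tp$uptake)
      meta[[tr]] <- scan_meta(animal_id, group, d_tr, tr, tp$dose,
                              tt$inj, tt$scan, spec$weight_g, spec$half_life_min)
      cls <- true_classes(tr, d_tr, s)
      n_aer <- an$n_lung - n_les_tr - n_halo_tr
      lung_mean <- (n_aer * cls$aerated + n_les_tr * cls$lesion +
                      n_halo_tr * cls$halo) / an$n_lung
      lung_mass_g <- an$n_lung * voxel_volume_ml(spec$spacing)  # 1 g/mL
      truth_cls[[tr]] <- list(
        day = d_tr, scan_mult = s,
        aerated_idg = cls$aerated, lesion_idg = cls$lesion,
        halo_idg = if (tr == "FMISO") cls$halo else NA_real_,
        lung_idg = lung_mean,
        lung_activity_MBq = lung_mean / 100 * cls$dose * lung_mass_g,
        blood_kbq_ml = cls$blood * cls$dose * 10)
    }
    entry$meta <- do.call(rbind, meta)
    entry$truth <- list(
      day = ses,
      burden = length(lesion_idx) / an$n_lung,
      lesion_voxels = length(lesion_idx), halo_voxels = length(halo_idx),
      lung_voxels = an$n_lung,
      lesion_idx = lesion_idx, halo_idx = halo_idx,
      tracers = truth_cls)
    out_sessions[[as.character(ses)]] <- entry
  }
  list(animal_id = animal_id, group = group,
       aggressiveness = a_i, baseline_jitter = e_i,
       anatomy = an, sessions = out_sessions)
}

#' Ground-truth label volume for one session
#'
#' 1 = aerated lung, 2 = halo, 3 = lesion, 0 elsewhere.
#' @param animal Output of [generate_animal()].
#' @param session Nominal session day.
#' @return Integer array.
#' @export
truth_labels <- function(animal, session) {
  an <- animal$anatomy
  tr <- animal$sessions[[as.character(session)]]$truth
  lab <- array(0L, an$dims)
  lab[an$lung_idx] <- 1L
  lab[tr$halo_idx] <- 2L
  lab[tr$lesion_idx] <- 3L
  lab
}

#' Generate and write a full synthetic cohort
#'
#' Simulates `n_per_group` animals per study group, writing one NIfTI
#' volume per scan, a study metadata table (CSV), per-animal ground
#' truth (JSON + label volumes) and the shared anatomy masks.
#'
#' @param spec A [phantom_spec()].
#' @param n_per_group Animals per group; scalar or vector in the order
#'   NaCl, BLM, BLM+pirfenidone, BLM+nintedanib.
#' @param out_dir Output directory (created if missing).
#' @param seed Base seed; each animal derives its own stream from it.
#' @param write_truth Also write truth JSON and label volumes.
#' @return The study table (invisibly), as written to
#'   `metadata.csv`.
#' @export
generate_cohort <- function(spec, n_per_group = c(4, 5, 5, 5),
                            out_dir, seed = spec$seed, write_truth = TRUE) {
  if (length(n_per_group) == 1) n_per_group <- rep(n_per_group, 4)
  stopifnot(length(n_per_group) == 4, all(n_per_group >= 1))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  codes <- c("NACL", "BLM", "PIRF", "NINT")
  an <- phantom_anatomy(spec)
  if (write_truth) {
    write_labels(an$lung_mask, spec$spacing, file.path(out_dir, "truth", "lung_mask.nii.gz"))
    bg <- array(FALSE, an$dims); bg[an$bg_idx] <- TRUE
    write_labels(bg, spec$spacing, file.path(out_dir, "truth", "background_roi.nii.gz"))
  }
  meta_all <- list(); k <- 0L
  for (g in seq_along(STUDY_GROUPS)) {
    for (i in seq_len(n_per_group[g])) {
      k <- k + 1L
      id <- sprintf("%s%02d", codes[g], i)
      animal <- generate_animal(spec, STUDY_GROUPS[g], id,
                                animal_seed = (as.numeric(seed) * 10000 + k) %% 2147483647)
      truth_out <- list(animal_id = id, group = STUDY_GROUPS[g],
                        aggressiveness = animal$aggressiveness,
                        baseline_jitter = animal$baseline_jitter,
                        sessions = list())
      for (ses in names(animal$sessions)) {
        entry <- animal$sessions[[ses]]
        day <- entry$session
        if (!is.null(entry$ct)) {
          f <- sprintf("%s_D%02d_CT.nii.gz", id, day)
          write_volume(entry$ct, file.path(out_dir, f))
          entry$meta$file[entry$meta$tracer == "CT"] <- f
        }
        for (tr in names(entry$pet)) {
          d_tr <- entry$truth$tracers[[tr]]$day
          f <- sprintf("%s_D%02d_%s.nii.gz", id, d_tr, tr)
          write_volume(entry$pet[[tr]], file.path(out_dir, f))
          entry$meta$file[entry$meta$tracer == tr] <- f
        }
        meta_all[[length(meta_all) + 1L]] <- entry$meta
        if (write_truth) {
          write_labels(truth_labels(animal, day), spec$spacing,
                       file.path(out_dir, "truth",
                                 sprintf("%s_D%02d_labels.nii.gz", id, day)))
          tr_rec <- entry$truth
          tr_rec$lesion_idx <- NULL; tr_rec$halo_idx <- NULL
          truth_out$sessions[[ses]] <- tr_rec
        }
      }
      if (write_truth)
        jsonlite::write_json(truth_out,
                             file.path(out_dir, "truth", paste0(id, ".json")),
                             auto_unbox = TRUE, digits = NA)
    }
  }
  study <- do.call(rbind, meta_all)
  rownames(study) <- NULL
  write.csv(study, file.path(out_dir, "metadata.csv"), row.names = FALSE)
  invisible(study)
}
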