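test_that("disease trajectory follows the bleomycin time course", {
  spec <- phantom_spec()
  days <- 0:23
  expect_equal(disease_trajectory("NaCl", days, spec), rep(0, 24))
  expect_equal(disease_trajectory("BLM", 0, spec), 0)
  blm <- disease_trajectory("BLM", days, spec)
  expect_true(all(diff(blm) >= 0))                       # monotone
  expect_equal(blm[days <= spec$onset_day], rep(0, sum(days <= spec$onset_day)))
  expect_equal(max(blm), spec$peak_burden)               # plateau at peak
  expect_equal(blm[days == spec$peak_day], spec$peak_burden)
  for (g in c("BLM+pirfenidone", "BLM+nintedanib")) {
    trt <- disease_trajectory(g, days, spec)
    expect_equal(trt[days <= 9], blm[days <= 9])          # therapy starts D9
    expect_true(all(trt[days > 9] <= blm[days > 9]))
    expect_lt(disease_trajectory(g, 23, spec), disease_trajectory("BLM", 23, spec))
  }
  expect_error(disease_trajectory("saline", 9, spec), "saline")
  expect_error(disease_trajectory("BLM", 30, spec), "study window")
})

test_that("phantom spec invariants are enforced", {
  expect_error(phantom_spec(spacing = -0.25), "spacing")
  expect_error(phantom_spec(pet_noise_cv = -0.1), "variances")
  expect_error(phantom_spec(peak_burden = 1.2), "peak_burden")
  expect_error(phantom_spec(onset_day = 25), "study window")
  bad_therapy <- phantom_spec()$therapy
  bad_therapy$pirfenidone$growth_mult <- 1.5
  expect_error(phantom_spec(therapy = bad_therapy), "growth multiplier")
  expect_error(phantom_spec(shape = c(24, 24, 24)), "grid too small")
  expect_error(phantom_spec(fdg_dose_mbq = 0), "dose")
})

test_that("scan metadata is validated", {
  expect_error(scan_meta("A", "BLM", 9, "FDG", -1,
                         "2021-03-10T09:00:00", "2021-03-10T09:20:00", 20),
               "dose")
  expect_error(scan_meta("A", "BLM", 9, "FDG", 5,
                         "2021-03-10T09:20:00", "2021-03-10T09:00:00", 20),
               "precedes")
  expect_error(scan_meta("A", "sham", 9, "FDG", 5,
                         "2021-03-10T09:00:00", "2021-03-10T09:20:00", 20),
               "sham")
  expect_error(scan_meta("A", "BLM", 9, "FDG", 5,
                         "2021-03-10T09:00:00", "2021-03-10T09:20:00", 0),
               "weight")
})

test_that("generated animals honour the ground-truth geometry contract", {
  spec <- small_spec()
  ani <- generate_animal(spec, "BLM", "B1", animal_seed = 21)
  an <- ani$anatomy
  for (ses in names(ani$sessions)) {
    tr <- ani$sessions[[ses]]$truth
    expect_length(intersect(tr$lesion_idx, tr$halo_idx), 0)   # disjoint
    expect_true(all(tr$lesion_idx %in% an$lung_idx))
    expect_true(all(tr$halo_idx %in% an$lung_idx))
    expect_equal(tr$burden, length(tr$lesion_idx) / an$n_lung)
  }
  # lesions grow concentrically: earlier lesions are subsets of later
  expect_true(all(ani$sessions[["9"]]$truth$lesion_idx %in%
                    ani$sessions[["16"]]$truth$lesion_idx))
  expect_true(all(ani$sessions[["16"]]$truth$lesion_idx %in%
                    ani$sessions[["23"]]$truth$lesion_idx))
  # the day-9 halo pre-figures later consolidation
  new_lesion <- setdiff(ani$sessions[["23"]]$truth$lesion_idx,
                        ani$sessions[["9"]]$truth$lesion_idx)
  frac_in_halo <- mean(new_lesion %in% ani$sessions[["9"]]$truth$halo_idx)
  expect_gte(frac_in_halo, 0.8)
  # FMISO-avid voxels (lesion + halo) outnumber FDG-avid voxels at day 9
  # (FDG uptake has not switched on yet)
  t9 <- ani$sessions[["9"]]$truth
  n_fmiso_avid <- length(t9$lesion_idx) + length(t9$halo_idx)
  expect_gt(n_fmiso_avid, 0)
  expect_lt(t9$tracers$FDG$lesion_idg, t9$tracers$FMISO$lesion_idg)
  expect_equal(t9$tracers$FDG$lesion_idg, t9$tracers$FDG$aerated_idg)  # FDG off at D9
})

test_that("controls carry no lesions and generation is deterministic", {
  spec <- small_spec()
  ctrl <- generate_animal(spec, "NaCl", "N1", animal_seed = 5)
  for (ses in names(ctrl$sessions)) {
    expect_equal(ctrl$sessions[[ses]]$truth$burden, 0)
    expect_length(ctrl$sessions[[ses]]$truth$halo_idx, 0)
  }
  again <- generate_animal(spec, "NaCl", "N1", animal_seed = 5)
  expect_identical(ctrl$sessions[["23"]]$ct$data, again$sessions[["23"]]$ct$data)
  b1 <- generate_animal(spec, "BLM", "B1", animal_seed = 77)
  b2 <- generate_animal(spec, "BLM", "B1", animal_seed = 77)
  expect_identical(b1$sessions[["9"]]$pet$FMISO$data, b2$sessions[["9"]]$pet$FMISO$data)
  expect_identical(b1$sessions[["23"]]$ct$data, b2$sessions[["23"]]$ct$data)
})

test_that("cohorts are written completely and load back", {
  dir <- withr::local_tempdir()
  spec <- small_spec()
  study <- generate_cohort(spec, n_per_group = 1, out_dir = dir, seed = 9)
  # 4 animals x 4 sessions x (1 CT + 2 PET) scans
  expect_equal(nrow(study), 4 * 4 * 3)
  vols <- list.files(dir, pattern = "_D\\d+_(CT|FDG|FMISO)\\.nii\\.gz$")
  expect_length(vols, 48)
  loaded <- load_study(file.path(dir, "metadata.csv"))
  expect_setequal(unique(loaded$group), fibroPET:::STUDY_GROUPS)
  expect_true(all(file.exists(file.path(dir, "truth",
                                        paste0(unique(loaded$animal_id), ".json")))))
  lab <- read_labels(file.path(dir, "truth", "lung_mask.nii.gz"))
  expect_equal(sum(lab > 0), sum(truth_lung_mask_for(spec)))
  suppressWarnings(
    expect_error(generate_cohort(spec, 1, out_dir = "/dev/null/nope"), "directory"))
})

test_that("early FMISO uptake rank-orders animals like final burden", {
  # per-animal aggressiveness drives both the day-9 halo signal and the
  # day-23 lesion load, so their rank orders coincide
  spec <- small_spec()
  fmiso9 <- burden23 <- numeric(5)
  for (i in 1:5) {
    ani <- generate_animal(spec, "BLM", paste0("B", i), animal_seed = 900 + i,
                           sessions = c(9, 23), tracers = "FMISO")
    fmiso9[i] <- ani$sessions[["9"]]$truth$tracers$FMISO$lung_idg
    burden23[i] <- ani$sessions[["23"]]$truth$burden
  }
  expect_identical(order(fmiso9), order(burden23))
})
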