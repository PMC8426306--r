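test_that("decay correction follows the half-life law", {
  expect_equal(decay_correct(1, 109.77, 109.77), 2)
  expect_equal(decay_correct(1, 0, 109.77), 1)
  expect_equal(decay_correct(4, 219.54, 109.77), 16)
  expect_error(decay_correct(1, -5, 109.77), "elapsed")
  expect_error(decay_correct(1, 5, 0), "half-life")
})

make_pet_volume <- function(values, spacing = 0.5) {
  volume_grid(values, spacing, "PET")
}

test_that("%ID/g and SUV reduce to their defining formulas", {
  pet <- make_pet_volume(array(250, c(2, 2, 2)))
  meta <- simple_meta(dose = 5, weight = 20)
  mask <- array(TRUE, c(2, 2, 2))
  pid <- percent_id_per_g(pet, meta, mask)
  expect_equal(unique(as.vector(pid$map)), 5)         # 100 * 0.25 / 5
  expect_equal(pid$lung_mean, 5)                      # homogeneity
  sv <- suv(pet, meta, mask)
  expect_equal(unique(as.vector(sv$map)), 1)          # 250 / (5000/20)
  expect_equal(sv$suv_mean, 1)
  bad <- meta; bad$dose_MBq <- 0
  expect_error(percent_id_per_g(pet, bad), "dose")
  bad2 <- meta; bad2$weight_g <- 0
  expect_error(suv(pet, bad2), "weight")
})

test_that("SUV equals %ID/g x weight / 100 on every voxel", {
  set.seed(8)
  pet <- make_pet_volume(array(runif(5^3, 0, 400), c(5, 5, 5)))
  meta <- scan_meta("A1", "BLM", 9, "FMISO", 10,
                    "2021-03-10T09:00:00", "2021-03-10T11:00:00", 20)
  pid <- percent_id_per_g(pet, meta)
  sv <- suv(pet, meta)
  expect_equal(sv$map, pid$map * meta$weight_g / 100, tolerance = 1e-12)
})

test_that("SUVmax picks the lung maximum", {
  vals <- array(0.1, c(3, 1, 1)); vals[, 1, 1] <- c(0.5, 1.2, 0.9) * 250
  sv <- suv(make_pet_volume(vals), simple_meta(), array(TRUE, c(3, 1, 1)))
  expect_equal(sv$suv_max, 1.2)
})

test_that("LTBR is a scale-invariant mean ratio", {
  map <- array(1, c(4, 4, 4))
  lung <- array(FALSE, c(4, 4, 4)); lung[1:2, , ] <- TRUE
  bg <- array(FALSE, c(4, 4, 4)); bg[4, , ] <- TRUE
  map[lung] <- 2
  expect_equal(lung_to_background_ratio(map, lung, bg), 2)
  expect_equal(lung_to_background_ratio(map * 7.3, lung, bg), 2)  # common factor cancels
  expect_error(lung_to_background_ratio(map, lung, array(FALSE, c(4, 4, 4))), "empty")
  expect_error(lung_to_background_ratio(map, lung, lung), "overlap")
  expect_error(lung_to_background_ratio(map * 0, lung, bg), "zero")
})

test_that("the MLV threshold is baseline mean + 2 sample SD", {
  thr <- mlv_threshold(c(0.4, 0.5, 0.6))
  expect_equal(thr$threshold, 0.7)       # sample SD is 0.1
  expect_equal(thr$baseline_sd, 0.1)
  expect_equal(mlv_threshold(c(0.37, 0.37))$threshold, 0.37)
  expect_error(mlv_threshold(0.4), ">= 2 baseline")
})

test_that("MLV counts strict exceedances and scales with voxel volume", {
  suv_map <- array(0, c(3, 1, 1)); suv_map[, 1, 1] <- c(0.5, 0.8, 1.0)
  mask <- array(TRUE, c(3, 1, 1))
  m <- metabolic_lung_volume(suv_map, mask, 0.7, spacing = c(2, 2, 2))
  expect_equal(m$mlv_ml, 2 * 0.008)
  expect_equal(m$mlv_pct, 100 * 2 / 3)
  expect_equal(metabolic_lung_volume(suv_map, mask, 1.0, c(2, 2, 2))$mlv_ml, 0)
  thrs <- seq(0, 1.2, by = 0.1)
  mlvs <- vapply(thrs, function(t)
    metabolic_lung_volume(suv_map, mask, t, c(2, 2, 2))$mlv_ml, 0)
  expect_true(all(diff(mlvs) <= 0))                    # monotone in threshold
})

test_that("HLV uses the 1.4 voxel-to-background ratio and rejects FDG", {
  map <- array(1, c(5, 1, 1)); map[, 1, 1] <- c(1.0, 1.5, 2.0, 1.0, 1.0)
  lung <- array(c(TRUE, TRUE, TRUE, FALSE, FALSE), c(5, 1, 1))
  bg <- array(c(FALSE, FALSE, FALSE, TRUE, TRUE), c(5, 1, 1))
  h <- hypoxic_lung_volume(map, lung, bg, spacing = c(2, 2, 2))
  expect_equal(h$hlv_ml, 2 * 0.008)                    # 1.5 and 2.0 >= 1.4
  uniform <- array(1, c(5, 1, 1))
  expect_equal(hypoxic_lung_volume(uniform, lung, bg, spacing = 0.5)$hlv_ml, 0)
  mults <- c(1.1, 1.4, 1.6, 2.1)
  hlvs <- vapply(mults, function(k)
    hypoxic_lung_volume(map, lung, bg, k, spacing = 0.5)$hlv_ml, 0)
  expect_true(all(diff(hlvs) <= 0))                    # monotone in multiplier
  expect_error(hypoxic_lung_volume(map, lung, bg, tracer = "FDG"), "FMISO")
})

test_that("density-gated uptake averages per class and flags absent classes", {
  hu <- array(-1000, c(3, 1, 1)); hu[, 1, 1] <- c(-500, -400, -50)
  ct <- volume_grid(hu, 0.5, "CT")
  mask <- array(TRUE, c(3, 1, 1))
  part <- partition_density(ct, mask)
  idg <- array(0, c(3, 1, 1)); idg[, 1, 1] <- c(1, 1, 3)
  g <- density_gated_uptake(idg, part)
  expect_equal(g$aerated_idg, 1)
  expect_equal(g$high_density_idg, 3)
  # all-aerated lung: the high-density class is missing, not zero
  hu2 <- array(-500, c(3, 1, 1))
  part2 <- partition_density(volume_grid(hu2, 0.5, "CT"), mask)
  expect_true(is.na(density_gated_uptake(idg, part2)$high_density_idg))
  expect_error(density_gated_uptake(idg[1:2, , , drop = FALSE], part), "grids")
})

test_that("metrics are invariant under voxel permutation", {
  set.seed(4)
  vals <- array(runif(4^3, 0, 300), c(4, 4, 4))
  meta <- simple_meta()
  perm <- sample(64)
  pvals <- array(vals[perm], c(4, 4, 4))
  mask <- array(TRUE, c(4, 4, 4))
  s1 <- suv(make_pet_volume(vals), meta, mask)
  s2 <- suv(make_pet_volume(pvals), meta, mask)
  expect_equal(s1$suv_mean, s2$suv_mean)
  expect_equal(s1$suv_max, s2$suv_max)
})

test_that("uptake recovered through the image chain matches the truth", {
  # uniform control lung, realistic PSF, no noise: closed-form oracle
  spec <- noiseless_spec()
  ani <- generate_animal(spec, "NaCl", "N", 6, sessions = 16)
  ses <- ani$sessions[["16"]]
  mask <- extract_lung_mask(ses$ct)
  for (tr in c("FDG", "FMISO")) {
    pid <- percent_id_per_g(ses$pet[[tr]], ses$meta[ses$meta$tracer == tr, ], mask)
    expect_equal(pid$lung_mean, ses$truth$tracers[[tr]]$lung_idg, tolerance = 0.01)
  }
  # with acquisition noise the recovery is within the noise CV
  spec2 <- small_spec()
  ani2 <- generate_animal(spec2, "NaCl", "N", 6, sessions = 16)
  ses2 <- ani2$sessions[["16"]]
  mask2 <- extract_lung_mask(ses2$ct)
  pid2 <- percent_id_per_g(ses2$pet$FDG, ses2$meta[ses2$meta$tracer == "FDG", ], mask2)
  expect_equal(pid2$lung_mean, ses2$truth$tracers$FDG$lung_idg,
               tolerance = spec2$pet_noise_cv)
})

test_that("baseline-anchored MLV threshold keeps control false positives rare", {
  # thresholds derive from all day-0 scans (every animal is healthy at
  # baseline); control follow-up scans should stay almost entirely below
  spec <- small_spec()
  suv0 <- c(); control <- list()
  for (i in 1:8) {
    g <- if (i <= 4) "NaCl" else "BLM"
    ani <- generate_animal(spec, g, paste0("A", i), animal_seed = 101 + i,
                           sessions = c(0, 16), tracers = "FDG")
    for (s in c("0", "16")) {
      ses <- ani$sessions[[s]]
      mask <- extract_lung_mask(ses$ct)
      sv <- suv(ses$pet$FDG, ses$meta[ses$meta$tracer == "FDG", ], mask)
      if (s == "0") suv0 <- c(suv0, sv$suv_mean)
      if (g == "NaCl") control[[paste(i, s)]] <- list(map = sv$map, mask = mask)
    }
  }
  thr <- mlv_threshold(suv0)
  false_pos <- vapply(control, function(sc) mean(sc$map[sc$mask] > thr$threshold), 0)
  expect_lt(mean(false_pos), 0.025)      # the 2-SD tail
})

test_that("density-gated uptake separates tracers as in fibrotic disease", {
  spec <- small_spec()
  bg <- background_mask_for(spec)
  blm <- generate_animal(spec, "BLM", "B", 55, sessions = c(9, 23))
  ctl <- generate_animal(spec, "NaCl", "N", 56, sessions = c(9, 23))
  q_blm23 <- quantify_session(blm$sessions[["23"]]$ct, blm$sessions[["23"]]$pet,
                              blm$sessions[["23"]]$meta, bg)
  # established fibrosis: FDG concentrates in the consolidated class
  expect_gt(q_blm23$high_density_idg[q_blm23$tracer == "FDG"],
            q_blm23$aerated_idg[q_blm23$tracer == "FDG"])
  # early disease: FMISO is already elevated in still-aerated lung
  q_blm9 <- quantify_session(blm$sessions[["9"]]$ct, blm$sessions[["9"]]$pet,
                             blm$sessions[["9"]]$meta, bg)
  q_ctl9 <- quantify_session(ctl$sessions[["9"]]$ct, ctl$sessions[["9"]]$pet,
                             ctl$sessions[["9"]]$meta, bg)
  expect_gt(q_blm9$aerated_idg[q_blm9$tracer == "FMISO"],
            q_ctl9$aerated_idg[q_ctl9$tracer == "FMISO"])
})
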