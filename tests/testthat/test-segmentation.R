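test_that("density classes follow the HU bands with a half-open split", {
  hu <- array(-1000, c(4, 4, 4))
  mask <- array(FALSE, c(4, 4, 4))
  vals <- c(-450, -50, 500, -800, -100, 300, -801, 301)
  mask[seq_along(vals)] <- TRUE
  hu[seq_along(vals)] <- vals
  ct <- volume_grid(hu, 0.5, "CT")
  part <- partition_density(ct, mask)
  got <- part$class[seq_along(vals)]
  #       -450 aerated; -50 high; 500 out; band edges: -800 aerated,
  #       -100 high (shared edge resolved to high density), 300 high,
  #       -801 and 301 out of band
  expect_equal(got, c(1L, 2L, 3L, 1L, 2L, 2L, 3L, 3L))
  expect_true(all(part$class[!mask] == 0L))
  expect_error(partition_density(ct, mask, bands = c(-100, -800, 300)), "bands")
  expect_error(partition_density(ct, mask[1:2, , ]), "mask"
  )
})

test_that("CT metrics reduce to their definitions", {
  hu <- array(0, c(3, 1, 1))
  hu[, 1, 1] <- c(-800, -500, -200)
  ct <- volume_grid(hu, c(2, 2, 2), "CT")
  mask <- array(TRUE, c(3, 1, 1))
  part <- partition_density(ct, mask)
  m <- ct_metrics(ct, part)
  expect_equal(m$mld_hu, -500)
  expect_equal(m$aerated_pct, 100)            # all three in [-800, -100)
  expect_equal(m$lung_volume_ml, 3 * 8 / 1000)
  # MLD is invariant to spacing; volume scales with voxel volume
  ct2 <- volume_grid(hu, c(1, 1, 1), "CT")
  m2 <- ct_metrics(ct2, partition_density(ct2, mask))
  expect_equal(m2$mld_hu, m$mld_hu)
  expect_equal(m2$lung_volume_ml, m$lung_volume_ml / 8)
  expect_error(ct_metrics(ct, partition_density(ct, array(FALSE, c(3, 1, 1)))),
               "empty")
})

test_that("no lung field is reported on uniform volumes", {
  body <- volume_grid(array(40, c(32, 32, 32)), 0.5, "CT")
  expect_error(extract_lung_mask(body), "no lung field found")
})

test_that("both disjoint lung fields are retained", {
  ct <- generate_animal(noiseless_spec(), "NaCl", "N", 3, sessions = 0,
                        tracers = "FDG")$sessions[["0"]]$ct
  mask <- extract_lung_mask(ct)
  expect_equal(attr(label_components(mask), "n"), 2L)
})

test_that("segmentation recovers the true lung field on noiseless scans", {
  spec <- noiseless_spec()
  truth <- truth_lung_mask_for(spec)
  for (case in list(list("NaCl", 0), list("NaCl", 23), list("BLM", 23))) {
    ani <- generate_animal(spec, case[[1]], "X", animal_seed = 31,
                           sessions = case[[2]], tracers = "FMISO")
    ses <- ani$sessions[[as.character(case[[2]])]]
    mask <- extract_lung_mask(ses$ct)
    expect_gte(dice(mask, truth), 0.95)
    part <- partition_density(ses$ct, mask)
    cm <- ct_metrics(ses$ct, part)
    expect_lt(abs(cm$aerated_pct - 100 * (1 - ses$truth$burden)), 2)
    # conservation: the density classes partition the lung mask
    expect_equal(sum(part$class > 0L), sum(mask))
  }
})

test_that("fibrotic lungs show higher density and fewer aerated voxels", {
  spec <- small_spec()
  blm <- generate_animal(spec, "BLM", "B", 13, sessions = 23,
                         tracers = "FMISO")$sessions[["23"]]
  ctl <- generate_animal(spec, "NaCl", "N", 14, sessions = 23,
                         tracers = "FMISO")$sessions[["23"]]
  m_blm <- ct_metrics(blm$ct, partition_density(blm$ct, extract_lung_mask(blm$ct)))
  m_ctl <- ct_metrics(ctl$ct, partition_density(ctl$ct, extract_lung_mask(ctl$ct)))
  expect_gt(m_blm$mld_hu, m_ctl$mld_hu)
  expect_lt(m_blm$aerated_pct, m_ctl$aerated_pct)
})

test_that("degradation-free chain reproduces tissue densities exactly", {
  spec <- exact_spec()
  ani <- generate_animal(spec, "NaCl", "N", 2, sessions = 23, tracers = "FMISO")
  ct <- ani$sessions[["23"]]$ct
  mask <- extract_lung_mask(ct)
  expect_gte(dice(mask, truth_lung_mask_for(spec)), 0.999)
  m <- ct_metrics(ct, partition_density(ct, mask))
  expect_equal(m$mld_hu, spec$hu_lung, tolerance = 1 / abs(spec$hu_lung))
})
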