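## CT lung segmentation and density-class partition.
##
## The lung field is recovered automatically: low-attenuation connected
## components interior to the body (air components touching the volume
## border are outside air), morphologically closed and hole-filled so
## dense consolidations enclosed by aerated lung are included.

#' Segmentation parameters
#'
#' @param lung_threshold_hu Voxels below this HU are lung-air
#'   candidates. Default −300 HU, near the midpoint between aerated lung
#'   (≈ −600 HU) and soft tissue (≈ +40 HU), which keeps the recovered
#'   boundary centred on the true edge under PSF blur.
#' @param min_volume_ml Minimum candidate component volume. Components
#'   below it are discarded as noise or airway fragments.
#' @param closing_radius Radius (voxels) of the morphological closing.
#' @param keep_components Maximum number of lung-field components kept
#'   (largest first). The default keeps every component above
#'   `min_volume_ml`: consolidation belts can split one lung's air space
#'   into several pieces, all of which belong to the lung field.
#' @export
seg_params <- function(lung_threshold_hu = -300, min_volume_ml = 0.01,
                       closing_radius = 2, keep_components = Inf) {
  list(lung_threshold_hu = lung_threshold_hu, min_volume_ml = min_volume_ml,
       closing_radius = closing_radius, keep_components = keep_components)
}

#' Extract the lung mask from a CT volume
#'
#' @param ct A CT `volume_grid` (Hounsfield units).
#' @param params A [seg_params()] list.
#' @return Logical 3D array; lung voxels are `TRUE`.
#' @export
extract_lung_mask <- function(ct, params = seg_params()) {
  stopifnot(inherits(ct, "volume_grid"))
  if (ct$modality != "CT") stop("lung segmentation expects a CT volume in HU")
  air <- ct$data < params$lung_threshold_hu
  lab <- label_components(air)
  n <- attr(lab, "n")
  if (n == 0L) stop("no lung field found")
  dm <- dim(lab)
  border <- unique(c(lab[c(1, dm[1]), , ], lab[, c(1, dm[2]), ], lab[, , c(1, dm[3])]))
  sizes <- tabulate(lab, nbins = n)
  sizes[intersect(border, seq_len(n))] <- 0L  # outside air
  min_vox <- params$min_volume_ml / voxel_volume_ml(ct)
  keep <- which(sizes >= min_vox)
  if (length(keep) == 0L) stop("no lung field found")
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  keep <- keep[seq_len(min(length(keep), params$keep_components))]
  mask <- array(lab %in% keep, dm)
  if (params$closing_radius > 0) mask <- close_mask(mask, params$closing_radius)
  fill_holes(mask)
}

#' Partition the lung into density classes
#'
#' Each lung voxel is classed by its HU value: aerated
#' `[bands[1], bands[2])`, high-density `[bands[2], bands[3]]`, and
#' out-of-band otherwise. The default bands are −800 to −100 HU
#' (aerated) and −100 to 300 HU (high density); the shared −100 HU edge
#' is resolved half-open so no voxel is counted twice.
#'
#' @param ct A CT `volume_grid`.
#' @param lung_mask Logical array from [extract_lung_mask()].
#' @param bands Ascending numeric length 3: aerated lower edge, class
#'   split, high-density upper edge.
#' @return A `lung_partition`: list with `lung_mask`, integer `class`
#'   array (0 outside lung, 1 aerated, 2 high density, 3 out of band),
#'   `bands` and `spacing`.
#' @export
partition_density <- function(ct, lung_mask, bands = c(-800, -100, 300)) {
  stopifnot(inherits(ct, "volume_grid"), is.array(lung_mask))
  if (!identical(dim(ct$data), dim(lung_mask)))
    stop("lung mask does not match the CT grid")
  if (length(bands) != 3 || is.unsorted(bands, strictly = TRUE))
    stop("density bands must be three strictly increasing HU values")
  cls <- array(0L, dim(lung_mask))
  hu <- ct$data[lung_mask]
  v <- ifelse(hu >= bands[1] & hu < bands[2], 1L,
              ifelse(hu >= bands[2] & hu <= bands[3], 2L, 3L))
  cls[lung_mask] <- v
  structure(list(lung_mask = lung_mask, class = cls, bands = bands,
                 spacing = ct$spacing),
            class = "lung_partition")
}

#' CT metrics over the lung
#'
#' Mean lung density (HU), aerated fraction (% of lung voxels) and lung
#' volume (mL).
#'
#' @param ct A CT `volume_grid`.
#' @param partition A `lung_partition`.
#' @return A one-row data frame with `mld_hu`, `aerated_pct`,
#'   `lung_volume_ml`.
#' @export
ct_metrics <- function(ct, partition) {
  stopifnot(inherits(partition, "lung_partition"))
  mask <- partition$lung_mask
  n <- sum(mask)
  if (n == 0) stop("empty lung mask")
  data.frame(
    mld_hu = mean(ct$data[mask]),
    aerated_pct = 100 * sum(partition$class == 1L) / n,
    lung_volume_ml = n * voxel_volume_ml(ct))
}
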