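## In-memory study pipeline: simulate -> segment -> quantify without
## touching disk. One animal is held in memory at a time, so full
## cohorts at the default grid stay light.

#' Simulate and quantify a cohort in memory
#'
#' Runs the full chain (phantom volumes, lung segmentation, CT and PET
#' quantification) for `n_per_group` animals per requested group and
#' returns the per-scan metrics table. Animal seeds are derived from
#' `seed` exactly as in [generate_cohort()], so the same seed yields the
#' same cohort whether or not volumes are written to disk.
#'
#' @param spec A [phantom_spec()].
#' @param n_per_group Animals per group (scalar or vector matching
#'   `groups`).
#' @param seed Base seed.
#' @param groups Study groups to simulate.
#' @param sessions Nominal session days to image.
#' @param tracers Tracers to image.
#' @param config A [pipeline_config()].
#' @return Per-scan metrics data frame (one CT row and one row per
#'   tracer per session); the phantom ground truth per animal/session is
#'   attached as attribute `truth`.
#' @export
cohort_metrics <- function(spec, n_per_group, seed = spec$seed,
                           groups = STUDY_GROUPS,
                           sessions = SESSION_DAYS, tracers = TRACERS,
                           config = pipeline_config()) {
  if (length(n_per_group) == 1) n_per_group <- rep(n_per_group, length(groups))
  stopifnot(length(n_per_group) == length(groups), all(n_per_group >= 1))
  an <- phantom_anatomy(spec)
  bg_mask <- array(FALSE, an$dims); bg_mask[an$bg_idx] <- TRUE
  out <- list(); truth <- list(); k <- 0L
  for (g in seq_along(groups)) {
    for (i in seq_len(n_per_group[g])) {
      k <- k + 1L
      id <- sprintf("%s%02d", gsub("[^A-Za-z]", "", groups[g]), i)
      animal <- generate_animal(spec, groups[g], id,
                                animal_seed = (as.numeric(seed) * 10000 + k) %% 2147483647,
                                sessions = sessions, tracers = tracers)
      for (ses in names(animal$sessions)) {
        entry <- animal$sessions[[ses]]
        out[[length(out) + 1L]] <-
          quantify_session(entry$ct, entry$pet, entry$meta, bg_mask, config)
        tr <- entry$truth; tr$lesion_idx <- NULL; tr$halo_idx <- NULL
        tr$animal_id <- id; tr$group <- groups[g]
        tr$aggressiveness <- animal$aggressiveness
        truth[[paste(id, ses, sep = "_D")]] <- tr
      }
    }
  }
  metrics <- do.call(rbind, out)
  rownames(metrics) <- NULL
  attr(metrics, "truth") <- truth
  metrics
}
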