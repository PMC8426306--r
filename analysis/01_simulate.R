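#!/usr/bin/env Rscript
# Step 1 — simulate the longitudinal dual-tracer study.
#
# Emulates the in-vivo design: 4 saline controls and 5 bleomycin mice
# per arm (vehicle, pirfenidone, nintedanib), imaged at baseline and on
# days 8/9, 15/16 and 22/23 with CT, FDG-PET and FMISO-PET. Volumes,
# metadata and ground truth are written under results/study/.
#
# Optional arguments: --n <per-group sizes, comma separated> --seed <int>

suppressMessages(library(fibroPET))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
n_per_group <- as.integer(strsplit(get_arg("--n", "4,5,5,5"), ",")[[1]])
seed <- as.integer(get_arg("--seed", "1"))

out_dir <- "results/study"
spec <- phantom_spec(seed = seed)
message(sprintf("Simulating %s animals (NaCl/BLM/pirfenidone/nintedanib) at %s voxels ...",
                paste(n_per_group, collapse = "/"),
                paste(spec$shape, collapse = "x")))
study <- generate_cohort(spec, n_per_group = n_per_group, out_dir = out_dir,
                         seed = seed)
message(sprintf("Wrote %d scans (%d animals x 4 sessions x 3 modalities) to %s",
                nrow(study), sum(n_per_group), out_dir))
message("Ground truth (burden, class uptake, label maps) is under ",
        file.path(out_dir, "truth"))
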