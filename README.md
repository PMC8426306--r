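# fibroPET

Quantification of longitudinal dual-tracer PET/CT studies of pulmonary
fibrosis in the mouse, with a digital thorax phantom for validation.

## The problem

In the intratracheal bleomycin model of lung fibrosis, consolidations
replace aerated lung during the fibrotic phase (days 7–23). Micro-CT
tracks established disease as rising mean lung density (MLD) and a
shrinking aerated fraction, and [18F]FDG-PET lights up metabolically
active fibrotic tissue — but both see disease that is already there.
Peri-lesional tissue that still looks normal on CT is hypoxic, and the
hypoxia tracer [18F]FMISO accumulates there *before* consolidation, so
early FMISO uptake is a candidate predictive biomarker of progression
and of response to the anti-fibrotic drugs pirfenidone and nintedanib.

fibroPET is for imaging scientists who need that analysis chain as
reproducible, tested code: CT lung segmentation, PET uptake metrics,
longitudinal biomarker statistics — plus a calibrated synthetic cohort
generator so the whole pipeline can be exercised without animal data.

## What it computes

For each scan (CT in Hounsfield units, PET in kBq/mL, with per-scan dose
and timing metadata):

* **Lung segmentation** — low-attenuation components interior to the
  body (threshold −300 HU), closed and hole-filled so consolidations
  enclosed by aerated lung are included; density partition into aerated
  [−800, −100) HU and high-density [−100, 300] HU classes; MLD, aerated
  fraction, lung volume.
* **Uptake metrics**, decay-corrected to injection time
  (A · 2^(t/T½), T½ = 109.77 min) with 1 g/mL tissue density:
  %ID/g = 100·C(MBq/mL)/dose; SUV = C/(dose/weight), so
  SUV = %ID/g·weight/100 voxelwise; lung-to-background ratio (LTBR);
  metabolic lung volume MLV (FDG voxels above the day-0 baseline
  threshold SUVmean + 2 SD); hypoxic lung volume HLV (FMISO voxels with
  voxel-to-background ratio ≥ 1.4); %ID/g gated by density class.
* **Longitudinal statistics** — progression score
  ΔCT = MLD(D23) − MLD(D9); group fold changes (MLD on the HU + 1000
  scale); Pearson correlations of day-9 markers with progression;
  exact Mann-Whitney and Kruskal-Wallis group comparisons; report
  tables (mean ± SEM) and time-course figures.

The phantom emulates the in-vivo study design (saline controls;
bleomycin ± pirfenidone/nintedanib from day 9; imaging at baseline and
days 8/9, 15/16, 22/23) and is calibrated so its ground-truth group
contrasts match the model's reported effect sizes — a 1.4-fold MLD
increase, 2.6-fold FDG and 3.2-fold FMISO uptake increase at established
fibrosis, with therapy ratios 1.2/2.9/2.6 (pirfenidone) and 1.2/2.3/2.5
(nintedanib). See `vignettes/fibropet-methods.Rmd` for the model, its
assumptions and its limitations.

## Worked example

Simulate a small cohort (4 animals per group, coarse 48³ grid for
speed), run the full pipeline in memory, and look at one bleomycin
animal and the group-level results:

```r
library(fibroPET)
spec <- phantom_spec(shape = c(48, 48, 48), spacing = 0.5, seed = 42)
metrics <- cohort_metrics(spec, n_per_group = 4, seed = 42, sessions = c(9, 23))
subset(metrics, animal_id == "BLM01",
       select = c(tracer, day, mld_hu, aerated_pct, lung_idg, ltbr, hlv_pct))
#>    tracer day mld_hu aerated_pct lung_idg ltbr hlv_pct
#> 25     CT   9   -563        95.0       NA   NA      NA
#> 26    FDG   8   -563        95.0     1.04 1.00      NA
#> 27  FMISO   9   -563        95.0     1.63 1.73    32.3
#> 28     CT  23   -462        80.3       NA   NA      NA
#> 29    FDG  22   -462        80.3     2.53 2.34      NA
#> 30  FMISO  23   -462        80.3     2.58 2.84    48.8
```

At day 9 this animal's lung is still 95% aerated and FDG is at
background (1.04 %ID/g, LTBR 1.0), but FMISO is already elevated
(1.63 %ID/g, 32% hypoxic lung volume) — the early-hypoxia signature. By
day 23 the lung has densified by ~100 HU and both tracers are high.
Group-mean fold changes at day 22/23 and day-9 predictive correlations:

```r
fold_change_table(metrics, session = 23)
#>              contrast   readout fold_change
#> 1            BLM/NaCl       MLD        1.36
#> 2            BLM/NaCl   FDG_idg        2.53
#> 3            BLM/NaCl FMISO_idg        2.73
#> 4 BLM/BLM+pirfenidone       MLD        1.15
#> 5 BLM/BLM+pirfenidone   FDG_idg        2.73
#> 6 BLM/BLM+pirfenidone FMISO_idg        2.19
#> 7  BLM/BLM+nintedanib       MLD        1.16
#> 8  BLM/BLM+nintedanib   FDG_idg        2.21
#> 9  BLM/BLM+nintedanib FMISO_idg        2.13

correlation_table(metrics)[1:3, ]
#>   group   marker     r     p n
#> 1   BLM   MLD_D9 -0.28 0.720 4
#> 2   BLM   FDG_D9  0.39 0.615 4
#> 3   BLM FMISO_D9  0.94 0.065 4
```

With only 4 animals per group the ratios scatter around the calibrated
effect sizes (they tighten at the default 96³ grid with n = 8), but the
structure is already visible: disease raises all three read-outs, both
drugs pull them back, and day-9 FMISO — not day-9 MLD or FDG — tracks
subsequent progression (r = 0.94 in the vehicle arm).

The same chain is available file-based: `generate_cohort()` writes
NIfTI volumes, a metadata CSV and ground truth; `load_study()` +
`quantify_study()` read and quantify them; `build_report()` emits the
study tables and figures. The numbered scripts under `analysis/` run
that workflow at the in-vivo cohort sizes (4/5/5/5) and leave their
outputs under `results/`.

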