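---
title: "Quantifying lung fibrosis with dual-tracer PET/CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lung fibrosis with dual-tracer PET/CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

In the intratracheal bleomycin (BLM) mouse model of pulmonary fibrosis, an
inflammatory phase (days 0–7) is followed by a fibrotic phase (days 7–23)
during which dense collagen-rich consolidations replace aerated lung.
Longitudinal micro-CT tracks this as rising mean lung density (MLD) and a
shrinking aerated fraction, but CT only sees tissue that has already
consolidated. Hypoxia precedes consolidation: peri-lesional tissue that still
looks normal on CT is already hypoxic and traps nitroimidazole tracers such as
[18F]FMISO, whereas [18F]FDG accumulates mainly in established, metabolically
active fibrotic tissue. A quantification chain that runs CT segmentation, PET
uptake metrics and longitudinal statistics can therefore ask two questions of
a dual-tracer study: *when* does each modality first separate disease from
control, and *does the early hypoxia signal predict later progression and
therapy response* (pirfenidone or nintedanib, dosed daily from day 9)?

fibroPET implements that chain end to end, together with a digital
mouse-thorax phantom so the whole pipeline can be exercised and validated
without animal data. Because no public imaging from this model is available,
the phantom is both the test fixture and the reference: its ground truth is
calibrated to the headline effect sizes reported for this model, and the
pipeline is judged by its ability to recover them *through the image chain*
(PSF blur, noise, automatic segmentation, decay correction).

## The quantification chain

**Lung segmentation.** Voxels below a threshold (default −300 HU) are air
candidates; connected components touching the volume border are outside air
and are removed; the remaining components above a minimum volume (default
0.01 mL) form the lung field, closed morphologically (radius 2 voxels) and
hole-filled so consolidations enclosed by aerated lung are included. The
−300 HU default sits near the midpoint between aerated lung (≈ −600 HU) and
soft tissue (≈ +40 HU); under a symmetric point-spread function the recovered
boundary is then centred on the true edge. A threshold well above the midpoint
(e.g. −200 HU) systematically inflates the mask by a fraction of a voxel of
blurred edge, which is why the midpoint value is the default. All components
above the minimum volume are kept because consolidation belts can split one
lung's air space into more than two pieces; keeping only the largest one or
two silently discards lung.

**Density partition.** Lung voxels are classed as aerated ([−800, −100) HU)
or high-density ([−100, 300] HU); the shared −100 HU edge is resolved
half-open so no voxel is counted twice, and voxels outside both bands remain
in the mask (they belong to the anatomical lung and contribute to MLD) but
are flagged out-of-band.

**PET metrics.** All quantification is decay-corrected to injection time
(activity × 2^(elapsed/half-life), fluorine-18 half-life 109.77 min) and
assumes soft-tissue density 1 g/mL:

* %ID/g = 100 × concentration (MBq/mL) / injected dose (MBq);
* SUV = concentration (kBq/mL) / (dose (kBq) / body weight (g)), so that
  SUV = %ID/g × weight / 100 voxelwise — an identity the tests assert;
* LTBR = lung mean / background-region mean (scale invariant);
* MLV (FDG only): lung volume with SUV strictly above the baseline threshold
  mean + 2 × sample SD of the per-animal day-0 SUVmean values;
* HLV (FMISO only): lung volume where the voxel-to-background ratio is at
  least 1.4;
* density-gated %ID/g: class means over the aerated and high-density
  partitions (an absent class is reported missing, not zero).

Two conventions deserve a note. The printed HLV rule is a scalar ratio times
1.4, but a scalar cannot define a voxel set; the voxelwise reading
(voxel ≥ 1.4 × background mean) is the standard FMISO convention and is what
the package implements, with the multiplier configurable. For MLV the "2 SD"
is taken across the baseline animals' SUVmean values (the threshold is
anchored at the cohort's day-0 scans); tie-breaks are strict ">" for MLV
(exceedance bound) and "≥" for HLV (ratio convention). The background region
for LTBR/HLV is deliberately explicit — a user-supplied mask, or the
paraspinal soft-tissue cylinder the phantom emits — because no anatomical
definition can be assumed for arbitrary data.

**Longitudinal statistics.** The progression score is ΔCT = MLD(day 23) −
MLD(day 9), with scans within ±1 day accepted (FDG and FMISO sessions sit on
consecutive days and are merged to nominal days 9/16/23). Fold changes are
ratios of group means; MLD fold changes are computed on the HU + 1000 scale, a
physical-density proxy that keeps ratios meaningful for negative HU values.
Predictive correlations are Pearson (linear fits; Spearman available).
Two-group comparisons use the two-sided Mann-Whitney test, computed by
exhaustive enumeration of all group assignments (ties included) for small
samples and the normal approximation beyond; more than two groups use
Kruskal-Wallis. No multiple-testing correction is applied; raw p-values carry
the `*`/`**`/`***` convention at 0.05/0.01/0.001. Results tables report
mean ± SEM.

## The phantom

**Anatomy.** An ellipsoid thorax (semi-axes 11 × 10 × 11.5 mm of +40 HU soft
tissue) contains two ellipsoid lung fields (3.8 × 5 × 7 mm at −600 HU,
centres ±5 mm lateral) and a paraspinal background cylinder used as the
reference region. Anatomy is fixed in millimetres across animals and grids;
the default grid is 96³ voxels at 0.25 mm.

**Disease.** Lesions are spherical consolidations (−30 HU) seeded at
2 blobs per lung toward the periphery (0.35–0.6 of the lung semi-axes) and
grown concentrically. The lesion volume fraction of the lung ("burden", the
collagen surrogate) ramps linearly from day 7 to a peak at day 16 and then
plateaus — the time course CT shows in this model. Per animal, the
post-day-9 growth is scaled by an "aggressiveness" multiplier
(truncated normal, mean 1, SD 0.25, range [0.3, 2]) and the pre-day-9 burden
by an independent 5% jitter. Therapy arms grow at 25% of the vehicle rate
from day 9. Blob radii are solved by bisection so the realised voxel count
matches the target burden; lesions are confined to the lung interior (1 mm
margin) so consolidations never merge into the chest wall — a simplification
(real consolidations do reach the pleura) that keeps HU-only automatic
segmentation exact and is the main respect in which passing tests understate
the difficulty of real data.

**Halo.** The FMISO-avid, CT-normal halo is the union of a 0.5 mm shell
around the current lesions and the region the lesions will occupy by day 23
under the animal's own trajectory. This construction makes the day-9 halo a
superset of later growth (every newly consolidated voxel was halo at day 9)
and couples halo extent to aggressiveness, which is exactly the mechanism by
which early FMISO uptake predicts progression in the simulated study. Halo
avidity is additionally scaled by 1 + coupling × (a − 1) with coupling 1 by
default, so the correlation survives any positive coupling.

**Uptake model.** Background tissue (body, blood, normal lung) sits at
1 %ID/g — an arbitrary but fixed convention, since only ratios are reported
for this model. Lesions take multiplier 6.71 (FDG, from day 15) or 8.40
(FMISO, from day 9); the halo takes 3.0 (FMISO only). Therapy scales the
uptake excess (multiplier − 1) per arm and tracer (pirfenidone 0 FDG / 0.23
FMISO; nintedanib 0.196 FDG / 0.279 FMISO) and, for pirfenidone FDG, the
whole-lung background by 0.897. That background factor is forced by
arithmetic: a vehicle/control ratio of 2.6 with a vehicle/treated ratio of
2.9 puts treated lungs *below* control uptake, which growth arrest alone
cannot produce.

**Calibration.** The free defaults were fixed once, analytically where
possible and numerically where geometry enters, so that the ground-truth
group contrasts at day 22/23 equal the model's reported effect sizes: MLD
ratio (HU + 1000) 1.4 and lung uptake ratios 2.6 (FDG) and 3.2 (FMISO) for
vehicle vs control, and 1.2/2.9/2.6 (pirfenidone), 1.2/2.3/2.5 (nintedanib)
for vehicle vs treated. The MLD algebra gives peak burden
(1000 − 600 + 570·b)/400 = 1.4 ⟹ b = 0.28 and the FDG multiplier
1 + 1.6/0.28; the FMISO multiplier and therapy avidity scales were solved
against halo-volume expectations measured over 80 simulated geometries.
These are model constants, not fitted per run; the pipeline is then required
to recover them through the image chain within the stochastic tolerance.

**Degradation.** Tissue HU texture (SD 15/50/60 for body/lung/lesion) is
added before the CT point-spread (FWHM 0.4 mm); post-reconstruction CT noise
is additive (SD 30 HU). PET acquisition noise (5% CV) is applied *before*
the PET point-spread (FWHM 1.2 mm), as in reconstructed PET where counting
noise is smoothed by the reconstruction kernel. This ordering matters: with
5% independent voxel noise added after the blur, the baseline-anchored MLV
threshold (mean + 2 SD across animals) could not keep control false positives
near the nominal 2-SD tail, because the threshold covers animal-level spread
only. Uptake variability is split into a stable per-animal multiplier
(CV 5.5%, shared by all of an animal's scans and therefore covered by the
baseline threshold) and day-to-day scan noise (CV 2%), both truncated normal
(±3σ) so the 2-SD tail is not inflated by skew. CT and PET carry separate
PSF widths because micro-CT resolution is an order of magnitude finer than
PET; a single 1.2 mm kernel would be wrong for CT.

PET volumes are stored as decay-*uncorrected* activity concentration at
acquisition start (kBq/mL), with injection/acquisition times in the metadata;
decay correction is an explicit, testable downstream step rather than a
baked-in assumption. Doses and uptake times follow the imaging protocol
(5 MBq FDG imaged +20 min; 10 MBq FMISO imaged +120 min), body weight is
fixed at 20 g (a convention; not reported per animal), and F-18's half-life
is the physical constant 109.77 min.

## What the synthetic study does and does not show

The phantom reproduces the statistical structure the analysis relies on:
density contrast between aerated and consolidated lung, the temporal
dissociation of the two tracers (FMISO separating groups from day 9, FDG
from day 15), therapy arrest from day 9, and the aggressiveness-mediated
coupling between early FMISO uptake and later progression. It does not
emulate respiratory motion, attenuation/scatter residuals, airway trees,
pleural contact of lesions, heart/liver uptake gradients, or
reconstruction artefacts; segmentation and quantification on real data are
correspondingly harder. Passing tests therefore validate the *computations*
(formulas, conventions, invariances, recovery through blur/noise), not
scanner-specific robustness.

## Problem sizes and numerical choices

Unit tests run the phantom at 48³ voxels (0.5 mm spacing — same anatomy,
coarser sampling); the fold-change recovery runs the default 96³ grid with
n = 8 per group; the prediction study uses 20 replicates of 10 bleomycin
animals at 48³. The lesion-radius bisection runs 40 iterations (volume
resolved to ~1 voxel); Gaussian blurs truncate at 4σ with row-renormalised
kernels (flux preserved in the interior); connected components use
6-connectivity; all random draws derive from one integer seed per animal, so
identical seeds give bit-identical volumes. Degenerate inputs error eagerly:
empty masks, zero doses or weights, overlapping masks, unknown groups,
missing timepoints and zero-variance correlations all name the offending
input rather than propagating NaN.

## Limitations

Known limitations beyond the phantom's realism: the automatic mask makes no
attempt to exclude hilar vessels or airways (the manual regions it replaces
may have); MLV/HLV depend on the background/baseline conventions described
above, so absolute volumes are comparable only within a convention; and the
fold-change calibration fixes group *means* — higher moments of the phantom
distributions are modelling choices, not fitted quantities.
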