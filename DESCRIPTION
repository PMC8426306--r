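Package: fibroPET
Title: Dual-Tracer PET/CT Quantification of Bleomycin Lung Fibrosis in the Mouse
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantification pipeline for longitudinal preclinical PET/CT
    studies of pulmonary fibrosis. Provides a digital mouse-thorax phantom
    emitting paired CT (Hounsfield units) and FDG/FMISO PET (activity
    concentration) volumes with ground truth; Hounsfield-unit lung
    segmentation with a density-class partition (aerated vs high-density);
    tracer uptake metrics (decay-corrected %ID/g, SUVmean/SUVmax,
    lung-to-background ratio, metabolic and hypoxic lung volumes,
    density-gated uptake); and longitudinal biomarker statistics
    (progression scores, group fold changes, predictive correlations,
    non-parametric group comparisons, study reports).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    oro.nifti,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
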