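Package: DECTmaps
Title: Dual-Energy CT Material Decomposition for Mineralized Tissue
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative dual-energy computed tomography (DECT) analysis of
    dense mineralized objects such as fossilized bone. Provides a forward
    simulator for paired low/high-kVp CT phantom volumes with known voxelwise
    composition, Gaussian noise and surface beam-hardening bands; calibration
    of three-material decomposition bases from dual-energy Hounsfield
    measurements of reference materials; per-voxel three-material
    decomposition into non-negative material maps (calcium, fluorine, iron)
    expressed in 135-kVp-equivalent Hounsfield units; and ROI-level
    quantification with one-way ANOVA, Bonferroni and Tukey HSD post-hoc
    comparisons for bone-versus-sediment, healthy-versus-diseased and
    geological age-trend contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, grDevices, RNifti, jsonlite, yaml, png
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
biocViews: Software, Visualization, Preprocessing
RoxygenNote: 7.3.3
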