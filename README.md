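# DECTmaps

Quantitative dual-energy CT (DECT) material decomposition for dense
mineralized objects such as fossilized bone, in R.

During fossilization, the hydroxyapatite of fresh bone is replaced by
fluorapatite and pore space is infilled by iron minerals. A dual-energy CT
scan measures each voxel at two tube voltages (80 and 135 kVp), and the
pair of Hounsfield values carries chemical information: every material
defines a direction through the origin of the dual-energy plane with
gradient g = HU₁₃₅/HU₈₀. `DECTmaps` implements a three-material
decomposition in that plane — for a voxel (L, H) with quotient q = H/L,
the two basis directions bracketing q (gradients g₁ < g₂ < g₃) are solved
exactly,

    c_A + c_B = L,    c_A·g_A + c_B·g_B = H,

with winner-take-all assignment outside the gradient fan and non-negative
map values c·g reported in 135-kVp-equivalent HU. The default fluorine
basis uses a calcium anchor (4248, 3000) HU, an iron anchor (10000, 7365)
HU and a fluorine gradient of 0.69 (the fluorite calibration quotient
3753/5432 rounded to two decimals). The package covers the full pipeline:

- **Phantom simulation** — paired 80/135-kVp volumes with known voxelwise
  composition, per-energy Gaussian noise, and surface beam-hardening bands
  (`phantomSpec`, `buildPhantom`, `addSurfaceArtifact`);
- **Calibration** — material quotients and decomposition bases from
  dual-energy measurements (`ingestMeasurements`, `buildFluorineBasis`,
  `buildCalciumBasis`);
- **Decomposition** — per-voxel maps (`decomposeVoxel`, `materialMap`);
- **Quantification** — ROI statistics, artifact screening, one-way ANOVA
  with Bonferroni/Tukey post-hoc tests, bone-vs-sediment and
  healthy-vs-diseased contrasts, and the geological age trend
  (`roiSummaries`, `anovaPosthoc`, `contrastStructures`, `ageTrend`);
- **I/O** — NIfTI-1 and NRRD volumes, basis JSON, PNG overlays, and an
  end-to-end demo pipeline (`readVolume`, `writeVolume`, `renderOverlay`,
  `runPipeline`).

Intended users are researchers applying clinical DECT scanners to
paleontological or other dense mineralized specimens, and anyone needing a
tested, self-contained reference implementation of image-domain
three-material decomposition.

## Worked example

```r
library(DECTmaps)

b <- buildFluorineBasis()
b
#> DecompositionBasis 'fluorine'
#>   fluorine     g = 0.6900  [gradient-only]
#>   calcium      g = 0.7062  [anchor (4248, 3000) HU]
#>   iron         g = 0.7365  [anchor (10000, 7365) HU]
#>   background threshold: 100 HU at 80 kVp

# a fluorite-like voxel splits into fluorine and calcium signal
round(decomposeVoxel(5432, 3753, b)$maps, 1)
#> fluorine  calcium     iron
#>   3538.7    214.3      0.0

# simulate the synthetic fossil cohort and test the age trend
coh <- simulateCohort(seed = 1)
fl <- coh[coh$element == "fluorine" & coh$structure == "bone", ]
tr <- ageTrend(fl)
tr$specimens
#>         specimen age_ma     mean
#> 1     bos_taurus    0.0 5.56e-02
#> 2   alcelaphinae    1.5 5.57e+02
#> 3      trex_arch   68.0 1.77e+03
#> 4 dysalotosaurus  153.0 3.55e+03
tr$monotone
#> [1] TRUE
```

The fluorine map of the extant bovine bone is ≈ 0 HU while the Late
Jurassic ornithopod reaches ≈ 3500 HU: bone fluorine rises monotonically
with geological age in the terrestrial specimens. Bone-vs-sediment
fluorine contrasts are highly significant for the terrestrial fossils
(e.g. p ≈ 1e-42 for the ornithopod) but not for the low-fluorine marine
ichthyosaur configuration (p ≈ 0.06), and the diseased region of the
theropod jaw phantom shows a strong focal fluorine excess over healthy
tissue. See the vignette
(`vignettes/dect-material-decomposition.Rmd`) for the model, parameter
and validation details.

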