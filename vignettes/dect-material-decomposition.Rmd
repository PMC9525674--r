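---
title: "Three-material dual-energy CT decomposition for mineralized tissue"
author: "DECTmaps authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-material dual-energy CT decomposition for mineralized tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DECTmaps)
```

## The problem

Fossilization replaces the hydroxyapatite of fresh bone with the more
stable fluorapatite: fluoride delivered by pore water substitutes for
hydroxyl ions in the bone mineral, and iron-bearing minerals infill pore
space. A dual-energy CT (DECT) scan acquires two co-registered attenuation
volumes of the same object at two tube voltages (here 80 and 135 kVp, in
Hounsfield units). Because photoelectric absorption and Compton scattering
depend differently on the effective atomic number, the *pair* of HU values
in a voxel carries chemical information that a single CT number does not.
`DECTmaps` turns that pair into per-voxel *material maps* — how much of the
voxel's signal is attributable to fluorine-bearing mineral, to
calcium-bearing mineral, or to iron — and quantifies the maps over regions
of interest (ROIs) with the conventional ANOVA/post-hoc statistics used in
comparative studies of bone and sediment.

## The decomposition model

Every material defines a direction through the origin of the dual-energy
plane, characterised by its gradient (quotient)

$$ g = \frac{\mathrm{HU}_{135\,\mathrm{kVp}}}{\mathrm{HU}_{80\,\mathrm{kVp}}}. $$

A three-material basis consists of three directions with distinct
gradients $g_1 < g_2 < g_3$, each given either by a measured anchor point
or by a gradient alone. The default fluorine basis uses a calcium anchor
(4248, 3000) HU, an iron anchor (10000, 7365) HU, and a fluorine gradient
of 0.69 — the measured fluorite quotient $3753/5432 = 0.691$ rounded to
two decimals:

```{r basis}
buildFluorineBasis()
```

For a voxel with measurements $(L, H)$ at (80, 135) kVp and quotient
$q = H/L$, the decomposition is a piecewise rule on $q$:

* $L \le \tau$ (background threshold, default 100 HU): background, all
  components zero;
* $q \le g_1$: the whole signal lies on direction 1 ($c_1 = L$);
* $g_1 < q < g_2$: solve exactly
  $c_1 + c_2 = L$, $c_1 g_1 + c_2 g_2 = H$ (closed 2×2 form), $c_3 = 0$;
* $g_2 \le q < g_3$: the analogous solve for the (2, 3) pair, $c_1 = 0$;
* $q \ge g_3$: the whole signal on direction 3.

The magnitudes $c_i$ live on the 80-kVp scale, and within a bracket they
conserve the voxel's 80-kVp HU exactly ($c_A + c_B = L$), a volume-style
conservation law that the test suite checks to machine precision. Reported
map values are $c_i\,g_i$, i.e. 135-kVp-equivalent HU, because descriptive
statistics of bone conventionally accompany the 135-kVp dataset. Map
values are clamped at zero; inside a bracket the solved components are
automatically non-negative, so clamping only acts at the fan boundaries.

Two aspects of this rule are deliberate design choices rather than
reproductions of a published algorithm, because commercial DECT
decompositions are proprietary: (i) *gradient bracketing* — each voxel is
explained by the two adjacent directions that bracket its quotient, never
by all three at once (an alternative would subtract an iron estimate
first); and (ii) conservation at the 80-kVp scale. The rule is fully
determined by published operating parameters (two anchors plus one
gradient) and reproduces the qualitative behaviour expected of such maps:
zero fluorine for voxels at or beyond the calcium gradient (fresh bone),
and large fluorine values for fluorapatite-like voxels.

```{r voxel}
decomposeVoxel(5432, 3753, buildFluorineBasis())$maps  # a fluorite-like voxel
```

The companion calcium basis (`buildCalciumBasis()`) stands in for the
clinical bone-mineral algorithm: calcite and measured iron-rod anchors
plus a soft-tissue direction of gradient 1.00 (water-like tissue
attenuates almost equally at both energies, and water is 0 HU at both by
definition). Two oddities of the calibration panel are handled as
documented irregularities: the printed calcite quotient 0.707 differs by
one ulp from the computed 3000/4248 = 0.706 (the package always computes),
and graphite's printed quotient fits only the inverted ratio, so graphite
is never used in a basis.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `fluorineGradient` | 0.69 | — | fluorine direction; fluorite quotient at 2 decimals |
| `calciumAnchor` | (4248, 3000) | HU | calcium direction (calcite measurement) |
| `ironAnchor` (fluorine basis) | (10000, 7365) | HU | iron direction as parameterised in the decomposition |
| `ironAnchor` (calcium basis) | (24422, 18311) | HU | measured iron-rod signature |
| `backgroundThreshold` | 100 | HU at 80 kVp | voxels at or below are background |
| `maxFraction` (ROI screening) | 0.05 | — | tolerated artifact-voxel fraction per ROI (strict) |
| `alpha` | 0.05 | — | two-sided significance level |

Note the two iron parameterisations: the decomposition algorithm's iron
direction (implied gradient 0.7365) is not the measured iron rod (0.750).
Both are kept in their respective printed roles; the rescaling between
them is not documented by the vendor, so the package does not attempt to
reconcile them.

## What the phantom generator emulates

`buildPhantom()` rasterises box/sphere/cylinder regions of constant
composition, evaluates the noiseless forward model — HU mixes linearly in
volume fractions, exactly the model the decomposition inverts — and adds
independent seeded Gaussian noise per energy (the two spirals of a
sequential dual-energy acquisition are independent measurements). Values
are clamped to the scanner range [−32768, 32767] HU. Beam hardening is
modelled as a constant HU offset in a surface band: all object voxels
within `bandWidth` voxels (city-block metric) of the object/background
interface, marked in an artifact mask so that ROI screening can exclude
them, mirroring the practice of placing ROIs in artifact-free areas.

The generator does **not** simulate projection-domain physics: no
polychromatic spectra, scatter, photon starvation, metal streaks, partial
volume at oblique interfaces, or reconstruction-kernel correlation between
neighbouring voxels. Passing tests therefore demonstrate the correctness
and statistical calibration of the decomposition and quantification
pipeline under its own forward model — not robustness to every artifact of
real scanner data.

Two default configurations define the package's study conditions:

* `fossilBonePhantomSpec()` — a single heavily mineralized bone
  (fluorapatite/calcite mixture, noiseless 3040 HU at 135 kVp) beside an
  iron-stained calcitic sediment, with voxel noise SD 542 HU at both
  energies and a 2-voxel, +400 HU surface band. This emulates the
  *conventional-CT* appearance of a large fossil on a clinical scanner,
  where the 135-kVp bone statistics are dominated by tissue heterogeneity
  and artifacts (mean ± SD ≈ 3040 ± 542 HU).
* `fossilCohortSpecs()` — seven specimens spanning extant to Middle
  Triassic, with voxel noise SD 10 HU. Material decomposition operates on
  smoothed reconstructions, and the fluorine—calcium bracket is only
  ≈ 0.016 wide in quotient: propagating bracket-scale noise through the
  clamped solve amplifies it ≈ 40-fold and *biases* ROI means (a voxel
  sitting at the calcium gradient would leak hundreds of HU of spurious
  fluorine at SD 90). A near-zero extant-bone fluorine map — the
  qualitative signature of fresh bone — is only reproducible with
  effective noise well below the bracket width, so 10 HU is the documented
  cohort default. The cohort's bone compositions are mixtures of three
  synthetic signatures (hydroxyapatite, fluorapatite, mudstone; see
  `?materialSignatures`) constructed from the decomposition geometry so
  that terrestrial fluorine rises monotonically with geological age from
  ≈ 0 HU (extant) to ≈ 3500 HU (Late Jurassic), marine specimens stay
  fluorine-poor, and the diseased-jaw phantom accumulates focal fluorine.

## Quantification and statistics

The unit of analysis is the ROI mean, ten box ROIs per structure by
default, matching the convention of ten structure-specific ROIs placed by
consensus. `placeROIs()` tiles boxes deterministically inside a structure
mask; `excludeArtifactROIs()` drops ROIs whose artifact fraction strictly
exceeds 5%. Descriptive statistics use the sample (n − 1) SD and
midpoint-median, reported as "mean ± SD HU; median, min–max HU".

Comparisons are classical equal-variance one-way ANOVA
(`stats::oneway.test`) with Bonferroni-adjusted pooled-variance pairwise
t tests ($p_{\mathrm{adj}} = \min(1, m\,p)$) and Tukey HSD
(`stats::TukeyHSD`), two-sided at $\alpha = 0.05$. With two groups the
ANOVA F equals the squared pooled t statistic exactly. Degenerate inputs
(all observations identical) return F = 0, p = 1 by convention. The test
suite verifies the type-I error rate of the ANOVA layer at $\alpha = 0.05$
over 2000 null simulations, and that Tukey is uniformly less conservative
than Bonferroni in balanced designs.

`ageTrend()` orders specimens by geological age and checks monotone
non-decrease of terrestrial fluorine means over all strictly age-ordered
pairs (specimens of equal age impose no ordering on each other); it
deliberately stops short of regressing fluorine on absolute age, since
fluorine uptake depends on the diagenetic setting, not time alone.

## Numerical choices and degenerate inputs

* Quotients are computed at full precision and rounded half-even only for
  display and for deriving the 0.69 default gradient.
* Bases reject gradients closer than $10^{-6}$ (degenerate geometry).
* The background threshold is inclusive: a voxel at exactly 100 HU at
  80 kVp is background. The bracket boundaries assign $q = g_2$ to the
  (2, 3) pair, so a voxel exactly on the calcium direction carries exactly
  zero fluorine.
* Region overlap in a phantom spec is an error; uncovered voxels become
  background. Volume fractions must sum to 1 within $10^{-9}$.
* ROI medians use the midpoint of the central pair; artifact exclusion is
  a strict inequality, so an ROI at exactly the threshold fraction is
  retained.

One numerical property matters for validation design: the fluorine map is
a *clamped ramp* in the measurement. For a mixture whose quotient sits at
the midpoint of the fluorine–calcium bracket, the two clamps are
symmetric about the operating point and Gaussian noise produces an
(essentially) unbiased ROI mean even when per-voxel noise far exceeds the
ramp width. The parameter-recovery check in the test suite uses exactly
this configuration — a fluorapatite/calcite bone at the mid-bracket
quotient (fraction computed at runtime with `mixtureForQuotient()`), a
64³ phantom, 90 HU noise per energy, ten ROIs of 14³ voxels — and
recovers the noiseless bone-ROI fluorine mean within 2%. Off-midpoint
mixtures under bracket-scale noise are measurably biased; that is a
property of any clamped estimator, not an implementation defect, and is
why the cohort uses small voxel noise (above).

## Problem sizes

The shipped experiments are sized for routine re-execution: the cohort
uses 44 × 24 × 12 grids with ten 4³-voxel ROIs per structure, the
parameter-recovery phantom is 64³, the round-trip property uses 10⁴
voxels, and the null calibration of the ANOVA layer uses 2000 replicates
of three groups of ten. All are the package's own validation choices and
complete in seconds on one core.

## Known limitations

* The decomposition explains each voxel by at most two materials (the
  bracketing pair); genuinely three-phase voxels are projected onto two
  directions.
* Everything is image-domain; raw-data (projection-domain) decomposition
  and virtual monoenergetic imaging are out of scope.
* Material maps are in 135-kVp-equivalent HU, not element mass fractions;
  absolute fluorine dating would require calibration against destructive
  chemistry.
* The beam-hardening model is a constant surface offset — adequate for
  testing ROI screening, not a physical artifact simulation.
* Effective atomic numbers (`effectiveZ`, Mayneord power law, exponent
  2.94) are informational; the bundled panel's chemist-supplied values do
  not match any common power-law exponent and are stored as given.
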