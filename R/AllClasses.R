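#' @import methods
NULL

# Scanner HU measurement range for the dual-energy acquisitions modelled here.
.HU_RANGE <- c(-32768, 32767)

#' DualEnergyVolume: paired co-registered low/high-kVp CT volumes
#'
#' Container for a pair of co-registered scalar CT volumes acquired (or
#' simulated) at 80 kVp and 135 kVp, with grid metadata. Phantom volumes
#' additionally carry a ground-truth region labelling with per-region material
#' compositions, and a logical mask of voxels contaminated by the simulated
#' surface beam-hardening band.
#'
#' @slot low 3-d numeric array, 80-kVp volume in Hounsfield units (HU).
#' @slot high 3-d numeric array, 135-kVp volume in HU; same dimensions as
#'   \code{low}.
#' @slot spacing numeric(3), voxel spacing in mm per axis.
#' @slot truth list with elements \code{labels} (integer array of region
#'   codes, 0 = background) and \code{compositions} (named list mapping region
#'   code to a named volume-fraction vector), or an empty list when no ground
#'   truth is available.
#' @slot artifactMask logical array marking artifact-contaminated voxels, or
#'   \code{NULL}.
#'
#' @seealso \code{\link{buildPhantom}}, \code{\link{addSurfaceArtifact}},
#'   \code{\link{materialMap}}
#' @exportClass DualEnergyVolume
setClass("DualEnergyVolume",
  representation(
    low = "array",
    high = "array",
    spacing = "numeric",
    truth = "list",
    artifactMask = "ANY"
  ),
  prototype(truth = list(), artifactMask = NULL)
)

setValidity("DualEnergyVolume", function(object) {
  msg <- character()
  if (!identical(dim(object@low), dim(object@high)))
    msg <- c(msg, "low and high volumes must have identical dimensions")
  if (length(dim(object@low)) != 3L)
    msg <- c(msg, "volumes must be 3-d arrays")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive finite values (mm)")
  rng <- range(object@low, object@high, finite = TRUE)
  if (rng[1] < .HU_RANGE[1] || rng[2] > .HU_RANGE[2])
    msg <- c(msg, sprintf("HU values must lie within [%d, %d]",
                          .HU_RANGE[1], .HU_RANGE[2]))
  if (!is.null(object@artifactMask)) {
    if (!is.logical(object@artifactMask) ||
        !identical(dim(object@artifactMask), dim(object@low)))
      msg <- c(msg, "artifactMask must be a logical array matching the grid")
  }
  if (length(object@truth)) {
    lab <- object@truth$labels
    if (is.null(lab) || !identical(dim(lab), dim(object@low)))
      msg <- c(msg, "truth$labels must match the volume grid")
  }
  if (length(msg)) msg else TRUE
})

#' PhantomSpec: specification of a synthetic dual-energy phantom
#'
#' Describes a voxel grid, a set of non-overlapping geometric regions with
#' constant material composition each, per-energy additive Gaussian noise
#' levels, an optional surface beam-hardening band, and a seed.
#'
#' @slot gridShape integer(3), voxel counts per axis.
#' @slot voxelSpacing numeric(3), mm per axis.
#' @slot regions list of region descriptors created with \code{\link{regionBox}},
#'   \code{\link{regionSphere}} or \code{\link{regionCylinder}}.
#' @slot noiseSDLow,noiseSDHigh HU standard deviation of the additive Gaussian
#'   voxel noise in the 80-kVp and 135-kVp volume respectively.
#' @slot artifact list with elements \code{bandWidth} (voxels) and
#'   \code{offsetHU}; a zero band width disables the artifact.
#' @slot seed integer seed used by \code{\link{buildPhantom}}.
#'
#' @seealso \code{\link{phantomSpec}}, \code{\link{buildPhantom}}
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    gridShape = "integer",
    voxelSpacing = "numeric",
    regions = "list",
    noiseSDLow = "numeric",
    noiseSDHigh = "numeric",
    artifact = "list",
    seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
    msg <- c(msg, "gridShape must be three positive voxel counts")
  if (length(object@voxelSpacing) != 3L || any(object@voxelSpacing <= 0))
    msg <- c(msg, "voxelSpacing must be three positive values (mm)")
  if (object@noiseSDLow < 0 || object@noiseSDHigh < 0)
    msg <- c(msg, "noise SDs must be non-negative")
  for (r in object@regions) {
    comp <- r$composition
    if (is.null(names(comp)) || any(comp < 0))
      msg <- c(msg, sprintf("region '%s': composition must be named, >= 0",
                            r$label))
    else if (abs(sum(comp) - 1) > 1e-9)
      msg <- c(msg, sprintf("region '%s': volume fractions must sum to 1",
                            r$label))
  }
  if (!is.numeric(object@artifact$bandWidth) || object@artifact$bandWidth < 0)
    msg <- c(msg, "artifact band width must be >= 0")
  if (length(msg)) msg else TRUE
})

#' DecompositionBasis: three-material decomposition geometry
#'
#' An ordered set of three material directions in the dual-energy Hounsfield
#' plane. Each direction is characterised by its gradient
#' g = HU(135 kVp) / HU(80 kVp); a direction may be defined either by an
#' anchor point (a measured HU pair) or by a gradient alone. Materials are
#' stored sorted by ascending gradient.
#'
#' @slot name basis name, e.g. \code{"fluorine"} or \code{"calcium"}.
#' @slot materials character(3), material names in ascending-gradient order.
#' @slot gradients numeric(3), the ascending gradients.
#' @slot anchors 3 x 2 numeric matrix of (hu_low, hu_high) anchors in the same
#'   order; rows of \code{NA} for gradient-only components.
#' @slot backgroundThreshold HU at 80 kVp below which a voxel is treated as
#'   background (default 100).
#'
#' @seealso \code{\link{buildFluorineBasis}}, \code{\link{buildCalciumBasis}},
#'   \code{\link{decomposeVoxel}}
#' @exportClass DecompositionBasis
setClass("DecompositionBasis",
  representation(
    name = "character",
    materials = "character",
    gradients = "numeric",
    anchors = "matrix",
    backgroundThreshold = "numeric"
  )
)

setValidity("DecompositionBasis", function(object) {
  msg <- character()
  g <- object@gradients
  if (length(g) != 3L || any(!is.finite(g)) || any(g <= 0))
    msg <- c(msg, "exactly three finite positive gradients are required")
  if (is.unsorted(g, strictly = TRUE))
    msg <- c(msg, "gradients must be sorted strictly ascending")
  if (min(diff(sort(g))) < 1e-6)
    msg <- c(msg, "degenerate basis: gradients coincide within 1e-6")
  if (length(object@materials) != 3L || anyDuplicated(object@materials))
    msg <- c(msg, "three distinct material names are required")
  a <- object@anchors
  if (!identical(dim(a), c(3L, 2L)))
    msg <- c(msg, "anchors must be a 3 x 2 matrix")
  else for (i in 1:3) {
    if (!anyNA(a[i, ])) {
      if (a[i, 1] <= 0)
        msg <- c(msg, "anchor hu_low values must be positive")
      else if (abs(a[i, 2] / a[i, 1] - g[i]) > 1e-9 * max(1, g[i]))
        msg <- c(msg, sprintf("anchor for '%s' does not reproduce its gradient",
                              object@materials[i]))
    }
  }
  if (length(object@backgroundThreshold) != 1L ||
      !is.finite(object@backgroundThreshold))
    msg <- c(msg, "backgroundThreshold must be a single finite HU value")
  if (length(msg)) msg else TRUE
})

#' MaterialMap: per-voxel material signal volume
#'
#' Scalar volume of the signal attributed to one basis material by the
#' three-material decomposition, expressed in 135-kVp-equivalent HU and
#' clamped at zero.
#'
#' @slot values 3-d numeric array of map values (HU, >= 0).
#' @slot material name of the mapped material.
#' @slot basis the \code{\linkS4class{DecompositionBasis}} used.
#' @slot spacing numeric(3), mm per axis, copied from the input volume.
#'
#' @seealso \code{\link{materialMap}}
#' @exportClass MaterialMap
setClass("MaterialMap",
  representation(
    values = "array",
    material = "character",
    basis = "DecompositionBasis",
    spacing = "numeric"
  )
)

setValidity("MaterialMap", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3-d array")
  if (any(object@values < 0, na.rm = TRUE))
    msg <- c(msg, "map values must be non-negative")
  if (!(object@material %in% object@basis@materials))
    msg <- c(msg, "material must be one of the basis materials")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive values (mm)")
  if (length(msg)) msg else TRUE
})

#' ROISet: labelled regions of interest with roles
#'
#' An integer label volume aligned with the analysed grid, plus a role table
#' describing each ROI code (structure, specimen, geological age, habitat) and
#' its exclusion status after artifact screening.
#'
#' @slot labels integer 3-d array; 0 = outside all ROIs, positive codes
#'   identify ROIs.
#' @slot roles data.frame with columns \code{code}, \code{structure},
#'   \code{specimen}, \code{age_ma}, \code{habitat}, \code{excluded},
#'   \code{reason}.
#' @slot spacing numeric(3), mm per axis.
#'
#' @seealso \code{\link{roiSet}}, \code{\link{placeROIs}},
#'   \code{\link{excludeArtifactROIs}}
#' @exportClass ROISet
setClass("ROISet",
  representation(labels = "array", roles = "data.frame", spacing = "numeric")
)

setValidity("ROISet", function(object) {
  msg <- character()
  codes <- sort(unique(object@labels[object@labels != 0L]))
  if (any(codes < 0))
    msg <- c(msg, "ROI codes must be positive")
  need <- c("code", "structure", "specimen", "age_ma", "habitat",
            "excluded", "reason")
  if (!all(need %in% names(object@roles)))
    msg <- c(msg, paste("roles must have columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(object@roles$code))
      msg <- c(msg, "each ROI code must map to exactly one role")
    if (!all(codes %in% object@roles$code))
      msg <- c(msg, "every label code must appear in the role table")
  }
  if (length(msg)) msg else TRUE
})

#' GroupComparison: one-way ANOVA with post-hoc tests
#'
#' Result container for a parametric one-way ANOVA with Bonferroni-adjusted
#' pairwise t tests and Tukey HSD post-hoc comparisons, at a two-sided
#' significance level.
#'
#' @slot groups group labels.
#' @slot n per-group sample sizes.
#' @slot F ANOVA F statistic.
#' @slot p ANOVA p value.
#' @slot df numeric(2), numerator and denominator degrees of freedom.
#' @slot pairwise data.frame with columns \code{group1}, \code{group2},
#'   \code{diff}, \code{p_raw}, \code{p_bonferroni}, \code{p_tukey},
#'   \code{significant} (two-sided, Bonferroni at \code{alpha}).
#' @slot alpha significance level (default 0.05).
#'
#' @seealso \code{\link{anovaPosthoc}}
#' @exportClass GroupComparison
setClass("GroupComparison",
  representation(
    groups = "character",
    n = "integer",
    F = "numeric",
    p = "numeric",
    df = "numeric",
    pairwise = "data.frame",
    alpha = "numeric"
  )
)

setValidity("GroupComparison", function(object) {
  msg <- character()
  if (!is.na(object@p) && (object@p < 0 || object@p > 1))
    msg <- c(msg, "p must lie in [0, 1]")
  pw <- object@pairwise
  if (nrow(pw) && any(pw$p_bonferroni + 1e-12 < pw$p_raw, na.rm = TRUE))
    msg <- c(msg, "Bonferroni-adjusted p must be >= raw p")
  if (length(msg)) msg else TRUE
})

#' ROISummary: descriptive statistics of one ROI
#'
#' @slot mean,sd,median,min,max descriptive statistics in HU; sd is the
#'   sample (n - 1) standard deviation.
#' @slot nVoxels number of voxels summarised.
#' @slot excluded whether the ROI was excluded from analysis.
#' @slot reason exclusion reason, or \code{""}.
#'
#' @seealso \code{\link{summarizeROI}}, \code{\link{formatROISummary}}
#' @exportClass ROISummary
setClass("ROISummary",
  representation(
    mean = "numeric", sd = "numeric", median = "numeric",
    min = "numeric", max = "numeric", nVoxels = "integer",
    excluded = "logical", reason = "character"
  ),
  prototype(excluded = FALSE, reason = "")
)

setValidity("ROISummary", function(object) {
  msg <- character()
  if (object@nVoxels < 1L)
    msg <- c(msg, "an ROI must contain at least one voxel")
  if (!is.na(object@sd) && object@sd < 0)
    msg <- c(msg, "sd must be >= 0")
  if (object@min > object@median || object@median > object@max)
    msg <- c(msg, "min <= median <= max must hold")
  if (length(msg)) msg else TRUE
})
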