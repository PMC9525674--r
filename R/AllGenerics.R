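#' Accessors for DECTmaps objects
#'
#' Accessor generics for the package's S4 containers. Slot access in user
#' code should always go through these.
#'
#' @param object a DECTmaps S4 object.
#' @return The corresponding component: numeric arrays for volume accessors,
#'   numeric vectors for spacing/gradients, a data.frame for roles/anchors.
#' @name accessors
#' @aliases lowEnergy highEnergy voxelSpacing truthLabels truthCompositions
#'   artifactMask gradients anchors basisMaterials backgroundThreshold
#'   mapValues roiLabels roiRoles
#' @examples
#' b <- buildFluorineBasis()
#' gradients(b)
#' basisMaterials(b)
NULL

#' @rdname accessors
#' @export
setGeneric("lowEnergy", function(object) standardGeneric("lowEnergy"))
#' @rdname accessors
#' @export
setGeneric("highEnergy", function(object) standardGeneric("highEnergy"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("truthLabels", function(object) standardGeneric("truthLabels"))
#' @rdname accessors
#' @export
setGeneric("truthCompositions",
           function(object) standardGeneric("truthCompositions"))
#' @rdname accessors
#' @export
setGeneric("artifactMask", function(object) standardGeneric("artifactMask"))
#' @rdname accessors
#' @export
setGeneric("gradients", function(object) standardGeneric("gradients"))
#' @rdname accessors
#' @export
setGeneric("anchors", function(object) standardGeneric("anchors"))
#' @rdname accessors
#' @export
setGeneric("basisMaterials", function(object) standardGeneric("basisMaterials"))
#' @rdname accessors
#' @export
setGeneric("backgroundThreshold",
           function(object) standardGeneric("backgroundThreshold"))
#' @rdname accessors
#' @export
setGeneric("mapValues", function(object) standardGeneric("mapValues"))
#' @rdname accessors
#' @export
setGeneric("roiLabels", function(object) standardGeneric("roiLabels"))
#' @rdname accessors
#' @export
setGeneric("roiRoles", function(object) standardGeneric("roiRoles"))

#' @rdname accessors
setMethod("lowEnergy", "DualEnergyVolume", function(object) object@low)
#' @rdname accessors
setMethod("highEnergy", "DualEnergyVolume", function(object) object@high)
#' @rdname accessors
setMethod("voxelSpacing", "DualEnergyVolume", function(object) object@spacing)
#' @rdname accessors
setMethod("voxelSpacing", "MaterialMap", function(object) object@spacing)
#' @rdname accessors
setMethod("voxelSpacing", "ROISet", function(object) object@spacing)
#' @rdname accessors
setMethod("truthLabels", "DualEnergyVolume", function(object) {
  if (!length(object@truth)) NULL else object@truth$labels
})
#' @rdname accessors
setMethod("truthCompositions", "DualEnergyVolume", function(object) {
  if (!length(object@truth)) NULL else object@truth$compositions
})
#' @rdname accessors
setMethod("artifactMask", "DualEnergyVolume", function(object) object@artifactMask)
#' @rdname accessors
setMethod("gradients", "DecompositionBasis", function(object) {
  structure(object@gradients, names = object@materials)
})
#' @rdname accessors
setMethod("anchors", "DecompositionBasis", function(object) {
  structure(object@anchors,
            dimnames = list(object@materials, c("hu_low", "hu_high")))
})
#' @rdname accessors
setMethod("basisMaterials", "DecompositionBasis", function(object) object@materials)
#' @rdname accessors
setMethod("backgroundThreshold", "DecompositionBasis",
          function(object) object@backgroundThreshold)
#' @rdname accessors
setMethod("mapValues", "MaterialMap", function(object) object@values)
#' @rdname accessors
setMethod("roiLabels", "ROISet", function(object) object@labels)
#' @rdname accessors
setMethod("roiRoles", "ROISet", function(object) object@roles)

setMethod("show", "DualEnergyVolume", function(object) {
  d <- dim(object@low)
  cat("DualEnergyVolume\n")
  cat(sprintf("  grid: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x ")))
  cat(sprintf("  80 kVp:  HU range [%.0f, %.0f]\n",
              min(object@low), max(object@low)))
  cat(sprintf("  135 kVp: HU range [%.0f, %.0f]\n",
              min(object@high), max(object@high)))
  if (length(object@truth))
    cat(sprintf("  truth: %d labelled regions\n",
                length(object@truth$compositions)))
  if (!is.null(object@artifactMask))
    cat(sprintf("  artifact mask: %d voxels flagged\n",
                sum(object@artifactMask)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec\n")
  cat(sprintf("  grid: %s voxels, spacing %s mm\n",
              paste(object@gridShape, collapse = " x "),
              paste(format(object@voxelSpacing, digits = 3), collapse = " x ")))
  cat(sprintf("  regions: %s\n",
              paste(vapply(object@regions, `[[`, "", "label"), collapse = ", ")))
  cat(sprintf("  noise SD (80/135 kVp): %.1f / %.1f HU; seed %d\n",
              object@noiseSDLow, object@noiseSDHigh, object@seed))
  if (object@artifact$bandWidth > 0)
    cat(sprintf("  surface artifact: band %d voxels, offset %+.0f HU\n",
                object@artifact$bandWidth, object@artifact$offsetHU))
})

setMethod("show", "DecompositionBasis", function(object) {
  cat(sprintf("DecompositionBasis '%s'\n", object@name))
  for (i in 1:3) {
    a <- object@anchors[i, ]
    src <- if (anyNA(a)) "gradient-only"
           else sprintf("anchor (%.0f, %.0f) HU", a[1], a[2])
    cat(sprintf("  %-12s g = %.4f  [%s]\n",
                object@materials[i], object@gradients[i], src))
  }
  cat(sprintf("  background threshold: %g HU at 80 kVp\n",
              object@backgroundThreshold))
})

setMethod("show", "MaterialMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("MaterialMap '%s' (basis '%s')\n",
              object@material, object@basis@name))
  cat(sprintf("  grid: %d x %d x %d voxels\n", d[1], d[2], d[3]))
  cat(sprintf("  values: [%.0f, %.0f] HU (135-kVp-equivalent), mean %.0f\n",
              min(object@values), max(object@values), mean(object@values)))
})

setMethod("show", "ROISet", function(object) {
  codes <- unique(object@labels[object@labels != 0L])
  cat(sprintf("ROISet: %d ROIs (%d excluded)\n",
              length(codes), sum(object@roles$excluded)))
  tab <- table(object@roles$structure)
  cat(sprintf("  structures: %s\n",
              paste(sprintf("%s (%d)", names(tab), tab), collapse = ", ")))
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison: %s\n", paste(object@groups, collapse = " vs ")))
  cat(sprintf("  one-way ANOVA: F(%g, %g) = %.4g, p = %.4g\n",
              object@df[1], object@df[2], object@F, object@p))
  if (nrow(object@pairwise)) {
    cat("  pairwise (Bonferroni / Tukey HSD):\n")
    for (i in seq_len(nrow(object@pairwise))) {
      pw <- object@pairwise[i, ]
      cat(sprintf("    %s - %s: diff %.4g, p = %.4g / %.4g%s\n",
                  pw$group1, pw$group2, pw$diff, pw$p_bonferroni, pw$p_tukey,
                  if (isTRUE(pw$significant)) " *" else ""))
    }
  }
})

setMethod("show", "ROISummary", function(object) {
  cat(formatROISummary(object), "\n")
})
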