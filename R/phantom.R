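#' Dual-energy material signatures for phantom simulation
#'
#' Each material is a direction in the dual-energy Hounsfield plane given by
#' its HU at 80 kVp and 135 kVp. The mineral rows (calcite, fluorite, sulfur,
#' iron, halite, graphite) are the measured calibration-panel signatures.
#' The tissue and sediment rows are synthetic signatures constructed from the
#' decomposition geometry so that phantoms emulate the dual-energy behaviour
#' of real specimens:
#' \itemize{
#'   \item \code{hydroxyapatite}: fresh (extant) bone mineral, 1658 HU at
#'     135 kVp and a quotient midway between the calcium and iron gradients,
#'     so decomposition attributes none of its signal to fluorine;
#'   \item \code{fluorapatite}: fully fluorinated bone mineral, 3500 HU at
#'     135 kVp with quotient 0.68, just below the fluorine gradient, so its
#'     entire signal is attributed to fluorine;
#'   \item \code{mudstone}: soft fluorine-free marine sediment with a
#'     quotient midway between the calcium and iron gradients.
#' }
#' The background material (air/void, 0 HU at both energies) closes every
#' composition to unit volume fraction.
#'
#' @return data.frame with columns \code{material}, \code{hu_low},
#'   \code{hu_high}.
#' @seealso \code{\link{forwardHU}}, \code{\link{buildPhantom}}
#' @examples
#' materialSignatures()
#' @export
materialSignatures <- function() {
  gCa <- 3000 / 4248
  gFe <- 7365 / 10000
  qMid <- (gCa + gFe) / 2
  data.frame(
    material = c("background", "calcite", "fluorite", "sulfur", "iron",
                 "halite", "graphite", "hydroxyapatite", "fluorapatite",
                 "mudstone"),
    hu_low = c(0, 4248, 5432, 3196, 24422, 1569, 325,
               1658 / qMid, 3500 / 0.68, 1100 / qMid),
    hu_high = c(0, 3000, 3753, 2153, 18311, 939, 381, 1658, 3500, 1100),
    stringsAsFactors = FALSE
  )
}

#' Noiseless forward model: HU of a material mixture
#'
#' First-order mixture rule: the HU of a voxel at each energy is the
#' volume-fraction-weighted sum of the component material HU values. This
#' linear model is exactly what the image-domain three-material decomposition
#' inverts; polychromatic spectral effects enter only through the
#' per-material two-energy signatures.
#'
#' @param composition named numeric vector of volume fractions (>= 0, summing
#'   to 1 within 1e-9).
#' @param signatures data.frame of material signatures as returned by
#'   \code{\link{materialSignatures}}.
#' @return numeric(2): \code{c(hu_low, hu_high)}.
#' @examples
#' forwardHU(c(calcite = 1))                      # (4248, 3000)
#' forwardHU(c(calcite = 0.5, background = 0.5))  # (2124, 1500)
#' @export
forwardHU <- function(composition, signatures = materialSignatures()) {
  stopifnot(is.numeric(composition), !is.null(names(composition)))
  if (any(composition < 0))
    stop("volume fractions must be >= 0")
  if (abs(sum(composition) - 1) > 1e-9)
    stop("volume fractions must sum to 1 (got ", format(sum(composition)), ")")
  idx <- match(names(composition), signatures$material)
  if (anyNA(idx))
    stop("unknown material(s): ",
         paste(names(composition)[is.na(idx)], collapse = ", "))
  c(hu_low = sum(composition * signatures$hu_low[idx]),
    hu_high = sum(composition * signatures$hu_high[idx]))
}

#' Region descriptors for phantom geometry
#'
#' Geometric primitives used in a \code{\linkS4class{PhantomSpec}}. All
#' coordinates are 1-based voxel indices (voxel centres); \code{lower} and
#' \code{upper} bounds are inclusive.
#'
#' @param label region label.
#' @param lower,upper integer(3), inclusive corner voxels of a box.
#' @param center numeric(3), centre voxel of a sphere or cylinder.
#' @param radius radius in voxels.
#' @param axis cylinder axis (1, 2 or 3).
#' @param halfLength half-length of the cylinder along its axis, in voxels.
#' @param composition named volume-fraction vector (>= 0, sums to 1).
#' @return A region descriptor list for use in \code{\link{phantomSpec}}.
#' @examples
#' regionBox("bone", c(3, 3, 3), c(12, 12, 12), c(fluorapatite = 1))
#' @name regions
NULL

#' @rdname regions
#' @export
regionBox <- function(label, lower, upper, composition) {
  stopifnot(length(lower) == 3L, length(upper) == 3L, all(upper >= lower))
  list(label = label, shape = "box", lower = as.numeric(lower),
       upper = as.numeric(upper), composition = composition)
}

#' @rdname regions
#' @export
regionSphere <- function(label, center, radius, composition) {
  stopifnot(length(center) == 3L, radius > 0)
  list(label = label, shape = "sphere", center = as.numeric(center),
       radius = as.numeric(radius), composition = composition)
}

#' @rdname regions
#' @export
regionCylinder <- function(label, center, radius, axis, halfLength,
                           composition) {
  stopifnot(length(center) == 3L, radius > 0, axis %in% 1:3, halfLength >= 0)
  list(label = label, shape = "cylinder", center = as.numeric(center),
       radius = as.numeric(radius), axis = as.integer(axis),
       halfLength = as.numeric(halfLength), composition = composition)
}

#' Construct a phantom specification
#'
#' @param gridShape integer(3), voxel counts per axis.
#' @param regions list of region descriptors (\code{\link{regionBox}} etc.).
#'   Regions must not overlap; uncovered voxels are background.
#' @param voxelSpacing numeric(3), mm per axis (default 0.5 mm isometric,
#'   a typical clinical reconstruction).
#' @param noiseSDLow,noiseSDHigh HU SD of the additive Gaussian voxel noise
#'   per energy.
#' @param artifactBandWidth width in voxels of the surface beam-hardening
#'   band (0 disables it).
#' @param artifactOffsetHU HU offset applied inside the band.
#' @param seed integer seed for \code{\link{buildPhantom}}.
#' @return A validated \code{\linkS4class{PhantomSpec}}.
#' @examples
#' phantomSpec(c(16, 16, 16),
#'             list(regionBox("bone", c(5, 5, 5), c(12, 12, 12),
#'                            c(calcite = 1))))
#' @export
phantomSpec <- function(gridShape, regions, voxelSpacing = c(0.5, 0.5, 0.5),
                        noiseSDLow = 0, noiseSDHigh = 0,
                        artifactBandWidth = 0, artifactOffsetHU = 0,
                        seed = 1L) {
  new("PhantomSpec",
      gridShape = as.integer(gridShape),
      voxelSpacing = as.numeric(voxelSpacing),
      regions = regions,
      noiseSDLow = as.numeric(noiseSDLow),
      noiseSDHigh = as.numeric(noiseSDHigh),
      artifact = list(bandWidth = as.integer(round(artifactBandWidth)),
                      offsetHU = as.numeric(artifactOffsetHU)),
      seed = as.integer(seed))
}

# Logical mask of one region on the grid.
.regionMask <- function(region, gridShape) {
  d <- gridShape
  switch(region$shape,
    box = {
      m <- array(FALSE, d)
      lo <- pmax(1, ceiling(region$lower))
      hi <- pmin(d, floor(region$upper))
      if (all(hi >= lo)) m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
      m
    },
    sphere = {
      cx <- region$center
      dx2 <- (seq_len(d[1]) - cx[1])^2
      dy2 <- (seq_len(d[2]) - cx[2])^2
      dz2 <- (seq_len(d[3]) - cx[3])^2
      array(outer(outer(dx2, dy2, `+`), dz2, `+`) <= region$radius^2, d)
    },
    cylinder = {
      cx <- region$center
      ax <- region$axis
      perp <- setdiff(1:3, ax)
      coords <- lapply(1:3, function(k) seq_len(d[k]))
      r2 <- outer(
        (coords[[perp[1]]] - cx[perp[1]])^2,
        (coords[[perp[2]]] - cx[perp[2]])^2, `+`)
      inAx <- abs(coords[[ax]] - cx[ax]) <= region$halfLength
      m <- array(FALSE, d)
      idx <- which(r2 <= region$radius^2, arr.ind = TRUE)
      if (nrow(idx)) for (k in which(inAx)) {
        pos <- matrix(0L, nrow(idx), 3)
        pos[, perp[1]] <- idx[, 1]
        pos[, perp[2]] <- idx[, 2]
        pos[, ax] <- k
        m[pos] <- TRUE
      }
      m
    },
    stop("unknown region shape: ", region$shape))
}

#' Simulate a paired dual-energy phantom volume
#'
#' Rasterises the spec's regions onto the grid (rejecting overlaps; voxels
#' covered by no region become background), evaluates the noiseless forward
#' model \code{\link{forwardHU}} per region, adds independent seeded Gaussian
#' noise to each energy volume, clamps to the scanner measurement range
#' [-32768, 32767] HU, and applies the surface beam-hardening band if
#' requested. The ground-truth region labelling and compositions, and the
#' artifact mask, are attached to the returned volume. Runs with the same
#' spec (including seed) are bit-identical.
#'
#' @param spec a \code{\linkS4class{PhantomSpec}}.
#' @param signatures material signature table (see
#'   \code{\link{materialSignatures}}).
#' @return A \code{\linkS4class{DualEnergyVolume}}.
#' @examples
#' sp <- phantomSpec(c(12, 12, 12),
#'                   list(regionBox("b", c(4, 4, 4), c(9, 9, 9),
#'                                  c(calcite = 1))))
#' vol <- buildPhantom(sp)
#' range(highEnergy(vol)[truthLabels(vol) == 1L])
#' @export
buildPhantom <- function(spec, signatures = materialSignatures()) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  d <- spec@gridShape
  labels <- array(0L, d)
  comps <- list()
  for (i in seq_along(spec@regions)) {
    reg <- spec@regions[[i]]
    m <- .regionMask(reg, d)
    if (any(labels[m] != 0L))
      stop("region '", reg$label, "' overlaps a previous region")
    labels[m] <- i
    comps[[as.character(i)]] <- reg$composition
  }
  low <- array(0, d)
  high <- array(0, d)
  for (i in seq_along(spec@regions)) {
    hu <- forwardHU(spec@regions[[i]]$composition, signatures)
    sel <- labels == i
    low[sel] <- hu[1]
    high[sel] <- hu[2]
  }
  if (spec@noiseSDLow > 0 || spec@noiseSDHigh > 0) {
    rs <- .saveRNG()
    on.exit(.restoreRNG(rs), add = TRUE)
    set.seed(spec@seed)
    n <- prod(d)
    if (spec@noiseSDLow > 0)
      low <- low + array(stats::rnorm(n, 0, spec@noiseSDLow), d)
    if (spec@noiseSDHigh > 0)
      high <- high + array(stats::rnorm(n, 0, spec@noiseSDHigh), d)
  }
  low <- pmin(pmax(low, .HU_RANGE[1]), .HU_RANGE[2])
  high <- pmin(pmax(high, .HU_RANGE[1]), .HU_RANGE[2])
  vol <- new("DualEnergyVolume", low = low, high = high,
             spacing = spec@voxelSpacing,
             truth = list(labels = labels, compositions = comps,
                          regionLabels = vapply(spec@regions, `[[`, "",
                                                "label")),
             artifactMask = array(FALSE, d))
  if (spec@artifact$bandWidth > 0)
    vol <- addSurfaceArtifact(vol, spec@artifact$bandWidth,
                              spec@artifact$offsetHU)
  vol
}

.saveRNG <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restoreRNG <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

# Erode a logical mask by one step of the 6-connected neighbourhood;
# voxels outside the grid count as FALSE (background).
.erode6 <- function(m) {
  d <- dim(m)
  out <- m
  shift <- function(m, axis, by) {
    r <- array(FALSE, d)
    n <- d[axis]
    if (by == 1L) idx <- list(src = 2:n, dst = 1:(n - 1))
    else idx <- list(src = 1:(n - 1), dst = 2:n)
    args_src <- args_dst <- rep(list(quote(expr = )), 3)
    args_src[[axis]] <- idx$src
    args_dst[[axis]] <- idx$dst
    r <- do.call(`[<-`, c(list(r), args_dst,
                          list(do.call(`[`, c(list(m), args_src)))))
    r
  }
  for (axis in 1:3) for (by in c(1L, -1L))
    out <- out & shift(m, axis, by)
  out
}

#' Add a surface beam-hardening band to a phantom volume
#'
#' Beam hardening biases HU near the surface of dense objects. This models
#' it as a constant HU offset applied, in both energy volumes, to all object
#' voxels within \code{bandWidth} voxels (city-block metric, 6-connected;
#' the grid boundary counts as background) of the object/background
#' interface. The artifact mask marks exactly those voxels; interior voxels
#' are untouched. The object is taken from the volume's ground-truth
#' labelling (any labelled region).
#'
#' @param vol a \code{\linkS4class{DualEnergyVolume}} carrying truth labels.
#' @param bandWidth band width in voxels (>= 0; 0 is a no-op).
#' @param offsetHU HU shift applied inside the band.
#' @return The modified \code{DualEnergyVolume} with an updated artifact
#'   mask.
#' @examples
#' sp <- phantomSpec(c(12, 12, 12),
#'                   list(regionBox("b", c(4, 4, 4), c(9, 9, 9),
#'                                  c(calcite = 1))))
#' vol <- addSurfaceArtifact(buildPhantom(sp), 1, 300)
#' sum(artifactMask(vol))
#' @export
addSurfaceArtifact <- function(vol, bandWidth, offsetHU) {
  stopifnot(is(vol, "DualEnergyVolume"), bandWidth >= 0)
  bandWidth <- as.integer(round(bandWidth))
  if (bandWidth == 0L) {
    if (is.null(vol@artifactMask))
      vol@artifactMask <- array(FALSE, dim(vol@low))
    return(vol)
  }
  lab <- truthLabels(vol)
  if (is.null(lab))
    stop("surface artifact requires ground-truth labels to locate the object")
  object <- lab > 0L
  eroded <- object
  for (k in seq_len(bandWidth)) eroded <- .erode6(eroded)
  band <- object & !eroded
  vol@low[band] <- pmin(pmax(vol@low[band] + offsetHU, .HU_RANGE[1]),
                        .HU_RANGE[2])
  vol@high[band] <- pmin(pmax(vol@high[band] + offsetHU, .HU_RANGE[1]),
                         .HU_RANGE[2])
  mask <- if (is.null(vol@artifactMask)) array(FALSE, dim(vol@low))
          else vol@artifactMask
  vol@artifactMask <- mask | band
  vol
}

#' Volume fraction of a two-material mixture with a target quotient
#'
#' Solves for the fraction a of material A such that the mixture
#' a * A + (1 - a) * B has dual-energy quotient \code{q}. Useful for placing
#' a mixture at a prescribed position between two basis gradients, e.g. at
#' the midpoint of a decomposition bracket.
#'
#' @param sigA,sigB numeric(2) signatures \code{c(hu_low, hu_high)}.
#' @param q target quotient HU(135)/HU(80).
#' @return The fraction of A, in [0, 1]; errors if the target quotient is
#'   not spanned by the two signatures.
#' @examples
#' s <- materialSignatures()
#' fa <- unlist(s[s$material == "fluorapatite", c("hu_low", "hu_high")])
#' ca <- unlist(s[s$material == "calcite", c("hu_low", "hu_high")])
#' mixtureForQuotient(fa, ca, 0.698)
#' @export
mixtureForQuotient <- function(sigA, sigB, q) {
  stopifnot(length(sigA) == 2L, length(sigB) == 2L, is.finite(q))
  num <- q * sigB[1] - sigB[2]
  den <- num - (q * sigA[1] - sigA[2])
  a <- unname(num / den)
  if (!is.finite(a) || a < 0 || a > 1)
    stop("target quotient is not spanned by the two signatures")
  a
}

#' Default fossil-bone-in-sediment phantom
#'
#' A single fossilized-bone phantom emulating the dual-energy statistics of
#' a heavily permineralized theropod bone measured on a clinical scanner:
#' the bone region is a fluorapatite/calcite mixture with a noiseless
#' 135-kVp value of 3040 HU and voxel noise of SD 542 HU at both energies,
#' embedded next to an iron-stained calcitic sediment block, with a
#' 2-voxel surface beam-hardening band of +400 HU.
#'
#' @param gridShape integer(3) grid (default 48 x 48 x 24).
#' @param noiseSDLow,noiseSDHigh voxel noise SD per energy (default 542 HU).
#' @param seed integer seed.
#' @return A \code{\linkS4class{PhantomSpec}} whose first region is the bone.
#' @examples
#' vol <- buildPhantom(fossilBonePhantomSpec(seed = 7))
#' mean(highEnergy(vol)[truthLabels(vol) == 1L])
#' @export
fossilBonePhantomSpec <- function(gridShape = c(48, 48, 24),
                                  noiseSDLow = 542, noiseSDHigh = 542,
                                  seed = 1L) {
  bone <- c(fluorapatite = 0.31509, calcite = 0.64573, background = 0.03918)
  sediment <- c(calcite = 0.45, iron = 0.01, background = 0.54)
  d <- gridShape
  xSplit <- floor(d[1] / 2)
  phantomSpec(
    gridShape = d,
    regions = list(
      regionBox("bone", c(3, 3, 3), c(xSplit - 2, d[2] - 2, d[3] - 2), bone),
      regionBox("sediment", c(xSplit + 2, 3, 3), c(d[1] - 2, d[2] - 2,
                                                   d[3] - 2), sediment)
    ),
    noiseSDLow = noiseSDLow, noiseSDHigh = noiseSDHigh,
    artifactBandWidth = 2, artifactOffsetHU = 400,
    seed = seed)
}

#' Specifications for the synthetic fossil cohort
#'
#' Seven phantom specimens emulating the study design of a dual-energy
#' survey of fossil and extant vertebrate bone: an extant bovine leg bone,
#' a Pleistocene antelope, a Late Cretaceous theropod (a fossilized
#' haemal arch and a diseased dentary with healthy and pathological tissue),
#' a Late Jurassic ornithopod, and two marine reptiles (an Early Jurassic
#' ichthyosaur and a Middle Triassic nothosaur). Bone compositions are
#' mixtures of the fluorapatite, hydroxyapatite and calcite signatures
#' chosen so that per-specimen fluorine-map means rise with geological age
#' in the terrestrial lineage (about 0 HU extant up to about 3500 HU at
#' 153 Ma), while the marine specimens stay fluorine-poor. Sediments are
#' iron-stained calcite (terrestrial) or mudstone (marine).
#'
#' Voxel noise defaults to 10 HU per energy, the effective noise of the
#' smoothed reconstructions on which material decomposition operates (see
#' the package vignette for why bracket-scale voxel noise would bias the
#' clamped fluorine maps).
#'
#' @param noiseSD voxel noise SD in HU applied to both energies of every
#'   specimen.
#' @param seed base seed; specimen i uses \code{seed * 100 + i}.
#' @return Named list; each element has \code{spec}
#'   (\code{\linkS4class{PhantomSpec}}), \code{structures} (region label ->
#'   structure role), \code{age_ma} and \code{habitat}.
#' @seealso \code{\link{simulateCohort}}
#' @export
fossilCohortSpecs <- function(noiseSD = 10, seed = 1L) {
  terrSediment <- c(calcite = 0.45, iron = 0.01, background = 0.54)
  marSediment <- c(mudstone = 0.85, background = 0.15)
  specimens <- list(
    bos_taurus = list(
      age_ma = 0, habitat = "terrestrial",
      regions = list(bone = c(hydroxyapatite = 1))),
    alcelaphinae = list(
      age_ma = 1.5, habitat = "terrestrial",
      regions = list(bone = c(fluorapatite = 0.25, hydroxyapatite = 0.65,
                              background = 0.10),
                     sediment = terrSediment)),
    trex_arch = list(
      age_ma = 68, habitat = "terrestrial",
      regions = list(bone = c(fluorapatite = 0.31509, calcite = 0.64573,
                              background = 0.03918))),
    trex_dentary = list(
      age_ma = 68, habitat = "terrestrial",
      regions = list(healthy = c(fluorapatite = 0.25, calcite = 0.75),
                     diseased = c(fluorapatite = 0.60, calcite = 0.35,
                                  background = 0.05))),
    dysalotosaurus = list(
      age_ma = 153, habitat = "terrestrial",
      regions = list(bone = c(fluorapatite = 1),
                     sediment = terrSediment)),
    ichthyosaur = list(
      age_ma = 175, habitat = "marine",
      regions = list(bone = c(hydroxyapatite = 0.8, background = 0.2),
                     sediment = marSediment)),
    nothosaurus = list(
      age_ma = 242, habitat = "marine",
      regions = list(bone = c(fluorapatite = 0.2, hydroxyapatite = 0.55,
                              background = 0.25),
                     sediment = marSediment))
  )
  out <- list()
  for (i in seq_along(specimens)) {
    sp <- specimens[[i]]
    nm <- names(specimens)[i]
    d <- c(44L, 24L, 12L)
    regs <- list()
    bounds <- list(c(3, 22), c(24, 43))  # x-extents of up to two regions
    for (j in seq_along(sp$regions)) {
      b <- bounds[[j]]
      regs[[j]] <- regionBox(names(sp$regions)[j],
                             c(b[1], 3, 2), c(b[2], 22, 11),
                             sp$regions[[j]])
    }
    out[[nm]] <- list(
      spec = phantomSpec(d, regs, noiseSDLow = noiseSD, noiseSDHigh = noiseSD,
                         seed = seed * 100L + i),
      structures = names(sp$regions),
      age_ma = sp$age_ma,
      habitat = sp$habitat)
  }
  out
}
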