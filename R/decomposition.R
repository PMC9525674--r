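#' Voxelwise dual-energy quotient
#'
#' The per-voxel analogue of the material quotient: HU(135)/HU(80), with
#' voxels at or below the background threshold at 80 kVp treated as
#' background (returned as \code{NA}); background is a value, not an error.
#'
#' @param huLow,huHigh numeric vectors/arrays of HU at 80 and 135 kVp.
#' @param backgroundThreshold HU at 80 kVp at or below which a voxel is
#'   background (default 100).
#' @return Numeric of the same shape; \code{NA} marks background voxels.
#' @examples
#' voxelQuotient(5432, 3753)   # fluorite-like voxel
#' voxelQuotient(50, 40)       # background -> NA
#' @export
voxelQuotient <- function(huLow, huHigh, backgroundThreshold = 100) {
  stopifnot(length(huLow) == length(huHigh))
  q <- ifelse(huLow <= backgroundThreshold, NA_real_, huHigh / huLow)
  if (!is.null(dim(huLow))) dim(q) <- dim(huLow)
  q
}

# Vectorised three-material decomposition core.
# Returns a list with `maps` (n x 3 matrix of map values c_i * g_i at the
# 135-kVp scale, clamped at 0) and `magnitudes` (n x 3 matrix of c_i at the
# 80-kVp scale), columns in the basis' ascending-gradient order.
#
# Rule on the quotient q relative to the sorted gradients g1 < g2 < g3:
#   background      -> all components zero
#   q <= g1         -> all signal to material 1 (c1 = hu_low)
#   g1 < q < g2     -> exact 2x2 solve of c1 + c2 = hu_low,
#                      c1 g1 + c2 g2 = hu_high; material 3 zero
#   g2 <= q < g3    -> analogous solve for the (2, 3) pair; material 1 zero
#   q >= g3         -> all signal to material 3 (c3 = hu_low)
.decomposeHU <- function(huLow, huHigh, basis) {
  g <- basis@gradients
  n <- length(huLow)
  mag <- matrix(0, n, 3, dimnames = list(NULL, basis@materials))
  q <- huHigh / huLow
  bg <- huLow <= basis@backgroundThreshold
  i1 <- !bg & q <= g[1]
  i12 <- !bg & q > g[1] & q < g[2]
  i23 <- !bg & q >= g[2] & q < g[3]
  i3 <- !bg & q >= g[3]
  mag[i1, 1] <- huLow[i1]
  if (any(i12)) {
    c2 <- (huHigh[i12] - g[1] * huLow[i12]) / (g[2] - g[1])
    mag[i12, 2] <- c2
    mag[i12, 1] <- huLow[i12] - c2
  }
  if (any(i23)) {
    c3 <- (huHigh[i23] - g[2] * huLow[i23]) / (g[3] - g[2])
    mag[i23, 3] <- c3
    mag[i23, 2] <- huLow[i23] - c3
  }
  mag[i3, 3] <- huLow[i3]
  maps <- sweep(mag, 2, g, `*`)
  maps[maps < 0] <- 0
  list(maps = maps, magnitudes = mag, background = bg)
}

#' Decompose a single dual-energy voxel into three materials
#'
#' Expresses one voxel's (HU 80 kVp, HU 135 kVp) measurement as a
#' combination of the basis' three material directions. The voxel quotient
#' is bracketed between the two adjacent gradients and the corresponding
#' 2x2 linear system is solved exactly; outside the gradient fan the whole
#' signal is assigned to the nearest extreme direction, and map values are
#' clamped at zero. Within a bracket the two 80-kVp magnitudes sum exactly
#' to the voxel's 80-kVp HU (volume-style conservation).
#'
#' @param huLow,huHigh the voxel's HU at 80 and 135 kVp.
#' @param basis a \code{\linkS4class{DecompositionBasis}}.
#' @return List with \code{magnitudes} (named numeric(3), 80-kVp scale),
#'   \code{maps} (named numeric(3), 135-kVp-equivalent HU, >= 0) and
#'   \code{background} (logical).
#' @examples
#' b <- buildFluorineBasis()
#' decomposeVoxel(5432, 3753, b)$maps   # fluorite-like voxel
#' decomposeVoxel(4248, 3000, b)$maps   # pure calcium anchor
#' @export
decomposeVoxel <- function(huLow, huHigh, basis) {
  stopifnot(is(basis, "DecompositionBasis"),
            length(huLow) == 1L, length(huHigh) == 1L)
  r <- .decomposeHU(huLow, huHigh, basis)
  list(magnitudes = r$magnitudes[1, ],
       maps = r$maps[1, ],
       background = unname(r$background[1]))
}

#' Compute a material map from a dual-energy volume
#'
#' Applies the three-material decomposition voxelwise to a co-registered
#' dual-energy volume and returns the map of one basis material in
#' 135-kVp-equivalent HU. Deterministic; grid metadata is preserved.
#'
#' @param vol a \code{\linkS4class{DualEnergyVolume}}.
#' @param basis a \code{\linkS4class{DecompositionBasis}}.
#' @param material which basis material to map (e.g. \code{"fluorine"});
#'   defaults to the basis' eponymous material if present, otherwise the
#'   first material.
#' @return A \code{\linkS4class{MaterialMap}}.
#' @examples
#' sp <- phantomSpec(c(8, 8, 8),
#'                   list(regionBox("b", c(2, 2, 2), c(7, 7, 7),
#'                                  c(fluorapatite = 1))))
#' fm <- materialMap(buildPhantom(sp), buildFluorineBasis(), "fluorine")
#' max(mapValues(fm))
#' @export
materialMap <- function(vol, basis, material = NULL) {
  stopifnot(is(vol, "DualEnergyVolume"), is(basis, "DecompositionBasis"))
  if (!identical(dim(vol@low), dim(vol@high)))
    stop("energy volumes have mismatched shapes")
  if (is.null(material))
    material <- if (basis@name %in% basis@materials) basis@name
                else basis@materials[1]
  if (!material %in% basis@materials)
    stop("material '", material, "' is not in basis '", basis@name, "' (",
         paste(basis@materials, collapse = ", "), ")")
  r <- .decomposeHU(as.vector(vol@low), as.vector(vol@high), basis)
  vals <- array(r$maps[, material], dim(vol@low))
  new("MaterialMap", values = vals, material = material, basis = basis,
      spacing = vol@spacing)
}
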