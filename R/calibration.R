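#' Bundled dual-energy calibration panel
#'
#' Dual-energy CT measurements of the reference materials used to calibrate
#' the three-material decomposition: mean HU of each material at 80 kVp and
#' 135 kVp on a clinical 320-row scanner, together with chemical formula and
#' effective atomic number. These solid high-purity materials (calcite,
#' fluorite, graphite, sulfur, iron, halite) cover the major elements of
#' fossilized bone mineral (fluorapatite) and its diagenetic environment.
#'
#' @return data.frame with columns \code{material}, \code{formula},
#'   \code{z_eff}, \code{hu_low} (80 kVp), \code{hu_high} (135 kVp).
#' @examples
#' ingestMeasurements(calibrationPanel())
#' @export
calibrationPanel <- function() {
  data.frame(
    material = c("calcite", "fluorite", "graphite", "sulfur", "iron",
                 "sodium_chloride"),
    formula = c("CaCO3", "CaF2", "C", "S", "Fe", "NaCl"),
    z_eff = c(15.88, 16.42, 6, 16, 26, 13.97),
    hu_low = c(4248, 5432, 325, 3196, 24422, 1569),
    hu_high = c(3000, 3753, 381, 2153, 18311, 939),
    stringsAsFactors = FALSE
  )
}

#' Dual-energy quotient of a material
#'
#' The quotient HU(135 kVp) / HU(80 kVp) characterises a material's spectral
#' behaviour: it is the gradient of the material's direction through the
#' origin of the dual-energy Hounsfield plane. Photoelectric-dominated
#' high-Z materials attenuate relatively more at 80 kVp and have quotients
#' below 1.
#'
#' @param huLow HU at 80 kVp; must be non-zero.
#' @param huHigh HU at 135 kVp.
#' @param digits decimals for half-even rounding of the returned quotient;
#'   \code{NULL} returns full precision.
#' @return The (optionally rounded) quotient.
#' @examples
#' computeQuotient(5432, 3753)        # fluorite, 0.691
#' computeQuotient(24422, 18311, 2)   # iron, 0.75
#' @export
computeQuotient <- function(huLow, huHigh, digits = 3) {
  stopifnot(is.numeric(huLow), is.numeric(huHigh),
            length(huLow) == length(huHigh))
  if (any(huLow == 0))
    stop("undefined quotient: hu_low is 0")
  q <- huHigh / huLow
  if (is.null(digits)) q else round(q, digits)  # round() is half-even
}

#' Ingest material calibration measurements
#'
#' Turns a table of per-material dual-energy HU measurements into calibration
#' entries carrying the derived material-specific quotient (gradient).
#' Materials with \code{hu_low <= 0} carry no quotient (the direction through
#' the origin is undefined or degenerate for them).
#'
#' @param rows data.frame with columns \code{material}, \code{hu_low},
#'   \code{hu_high} and optionally \code{formula}, \code{z_eff}. May also be
#'   a path to a CSV file with those columns.
#' @param digits decimals for the displayed quotient (default 3); the
#'   full-precision value is kept in \code{quotient_full}.
#' @return data.frame of calibration entries, input order preserved, with
#'   added columns \code{quotient} (rounded) and \code{quotient_full}.
#' @examples
#' cal <- ingestMeasurements(calibrationPanel())
#' cal[cal$material == "fluorite", "quotient"]  # 0.691
#' @export
ingestMeasurements <- function(rows, digits = 3) {
  if (is.character(rows) && length(rows) == 1L)
    rows <- utils::read.csv(rows, stringsAsFactors = FALSE)
  if (!is.data.frame(rows) || nrow(rows) == 0L)
    stop("calibration input must be a non-empty data.frame")
  need <- c("material", "hu_low", "hu_high")
  if (!all(need %in% names(rows)))
    stop("calibration input needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(rows$material))
    stop("duplicate material name(s): ",
         paste(unique(rows$material[duplicated(rows$material)]), collapse = ", "))
  if (any(!is.finite(rows$hu_low)) || any(!is.finite(rows$hu_high)))
    stop("HU measurements must be finite")
  ok <- rows$hu_low > 0
  qf <- rep(NA_real_, nrow(rows))
  qf[ok] <- rows$hu_high[ok] / rows$hu_low[ok]
  rows$quotient_full <- qf
  rows$quotient <- round(qf, digits)
  rows
}

# Shared constructor: components is a named list; each element is either
# list(anchor = c(hu_low, hu_high)) or list(gradient = g).
.makeBasis <- function(name, components, backgroundThreshold = 100) {
  stopifnot(length(components) == 3L, !is.null(names(components)))
  g <- numeric(3)
  a <- matrix(NA_real_, 3, 2)
  for (i in 1:3) {
    cm <- components[[i]]
    if (!is.null(cm$anchor)) {
      if (length(cm$anchor) != 2L || cm$anchor[1] <= 0)
        stop("anchor for '", names(components)[i],
             "' must be a positive (hu_low, hu_high) pair")
      a[i, ] <- cm$anchor
      g[i] <- cm$anchor[2] / cm$anchor[1]
    } else if (!is.null(cm$gradient)) {
      if (!is.finite(cm$gradient) || cm$gradient <= 0 || cm$gradient >= 2)
        stop("gradient for '", names(components)[i], "' must lie in (0, 2)")
      g[i] <- cm$gradient
    } else {
      stop("component '", names(components)[i],
           "' needs an anchor or a gradient")
    }
  }
  if (min(diff(sort(g))) < 1e-6)
    stop("degenerate basis: two material gradients coincide within 1e-6")
  ord <- order(g)
  new("DecompositionBasis",
      name = name,
      materials = names(components)[ord],
      gradients = g[ord],
      anchors = a[ord, , drop = FALSE],
      backgroundThreshold = backgroundThreshold)
}

#' Build the fluorine three-material decomposition basis
#'
#' Constructs the custom fluorine decomposition basis from a calcium anchor,
#' an iron anchor and a fluorine gradient. The defaults are the algorithm's
#' operating parameters: calcium (4248, 3000) HU, iron (10000, 7365) HU, and
#' a fluorine gradient of 0.69, which equals the measured fluorite quotient
#' 3753/5432 rounded to two decimals.
#'
#' @param calciumAnchor,ironAnchor numeric(2), (hu_low, hu_high) anchors with
#'   positive hu_low.
#' @param fluorineGradient gradient of the fluorine direction, in (0, 2).
#' @param backgroundThreshold HU at 80 kVp below which voxels are background.
#' @return A \code{\linkS4class{DecompositionBasis}} with gradients sorted
#'   ascending (fluorine < calcium < iron for the defaults).
#' @examples
#' b <- buildFluorineBasis()
#' gradients(b)
#' @export
buildFluorineBasis <- function(calciumAnchor = c(4248, 3000),
                               ironAnchor = c(10000, 7365),
                               fluorineGradient = 0.69,
                               backgroundThreshold = 100) {
  .makeBasis("fluorine",
             list(calcium = list(anchor = calciumAnchor),
                  iron = list(anchor = ironAnchor),
                  fluorine = list(gradient = fluorineGradient)),
             backgroundThreshold)
}

#' Build the calcium three-material decomposition basis
#'
#' A calcium-specific decomposition in the style of clinical bone-mineral
#' algorithms: calcite and iron anchors plus a soft-tissue direction of
#' gradient 1 (water-like tissue attenuates nearly equally at both energies,
#' and water is 0 HU at both by definition). The iron anchor here is the
#' measured iron-rod signature.
#'
#' @param calciteAnchor,ironAnchor numeric(2), (hu_low, hu_high) anchors.
#' @param softTissueGradient gradient of the soft-tissue direction.
#' @inheritParams buildFluorineBasis
#' @return A \code{\linkS4class{DecompositionBasis}} named \code{"calcium"}.
#' @examples
#' gradients(buildCalciumBasis())
#' @export
buildCalciumBasis <- function(calciteAnchor = c(4248, 3000),
                              ironAnchor = c(24422, 18311),
                              softTissueGradient = 1.00,
                              backgroundThreshold = 100) {
  .makeBasis("calcium",
             list(calcium = list(anchor = calciteAnchor),
                  iron = list(anchor = ironAnchor),
                  soft_tissue = list(gradient = softTissueGradient)),
             backgroundThreshold)
}

# Atomic numbers for elements that occur in the calibration materials and
# bone/sediment chemistry.
.ELEMENT_Z <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8,
                F = 9, Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16,
                Cl = 17, K = 19, Ca = 20, Ti = 22, Mn = 25, Fe = 26,
                Cu = 29, Zn = 30, Sr = 38, Ba = 56, Ce = 58)

#' Effective atomic number of a compound
#'
#' Power-law electron-fraction mean (Mayneord form):
#' \eqn{Z_{eff} = (\sum_i w_i Z_i^p)^{1/p}} where \eqn{w_i} is the electron
#' fraction of element \eqn{i} and \eqn{p} the exponent (default 2.94,
#' appropriate for the photoelectric regime). Informational metadata only;
#' the decomposition itself uses measured HU directions, not Z_eff.
#'
#' @param composition named numeric vector of atom counts per element symbol,
#'   e.g. \code{c(Ca = 1, C = 1, O = 3)} for calcite.
#' @param exponent power-law exponent p.
#' @return The effective atomic number.
#' @examples
#' effectiveZ(c(H = 2, O = 1))  # water, about 7.4
#' @export
effectiveZ <- function(composition, exponent = 2.94) {
  stopifnot(is.numeric(composition), length(composition) >= 1L,
            all(composition > 0))
  el <- names(composition)
  unknown <- setdiff(el, names(.ELEMENT_Z))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  z <- .ELEMENT_Z[el]
  w <- composition * z / sum(composition * z)  # electron fractions
  unname(sum(w * z^exponent)^(1 / exponent))
}

#' Serialize or restore a decomposition basis as JSON
#'
#' @param basis a \code{\linkS4class{DecompositionBasis}}.
#' @param path file path to write to / read from.
#' @return \code{writeBasis} returns \code{path} invisibly; \code{readBasis}
#'   returns the restored \code{DecompositionBasis}.
#' @examples
#' f <- tempfile(fileext = ".json")
#' writeBasis(buildFluorineBasis(), f)
#' readBasis(f)
#' @export
writeBasis <- function(basis, path) {
  stopifnot(is(basis, "DecompositionBasis"))
  comp <- lapply(seq_len(3), function(i) {
    if (anyNA(basis@anchors[i, ])) list(gradient = basis@gradients[i])
    else list(anchor = as.numeric(basis@anchors[i, ]))
  })
  names(comp) <- basis@materials
  jsonlite::write_json(
    list(name = basis@name, components = comp,
         background_threshold = basis@backgroundThreshold),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeBasis
#' @export
readBasis <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  comp <- lapply(x$components, function(cm) {
    if (!is.null(cm$anchor)) list(anchor = as.numeric(cm$anchor))
    else list(gradient = as.numeric(cm$gradient))
  })
  .makeBasis(x$name, comp, x$background_threshold)
}
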