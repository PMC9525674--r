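#' Read and write scalar CT volumes
#'
#' Lossless round-trip of voxel values, shape and spacing for the two
#' supported medical-image volume formats: NIfTI-1 (\code{.nii},
#' \code{.nii.gz}; via RNifti) and NRRD (\code{.nrrd}; a minimal
#' raw-encoded little-endian reader/writer, as no installed package covers
#' NRRD). The format is chosen from the file extension.
#'
#' @param path file path ending in \code{.nii}, \code{.nii.gz} or
#'   \code{.nrrd}.
#' @param values 3-d numeric array of HU values.
#' @param spacing numeric(3), mm per axis.
#' @return \code{readVolume}: list with \code{values} (3-d array) and
#'   \code{spacing}. \code{writeVolume}: \code{path}, invisibly.
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' writeVolume(array(rnorm(60), c(5, 4, 3)), f, spacing = c(0.5, 0.5, 1))
#' str(readVolume(f))
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    img <- RNifti::readNifti(path)
    vals <- array(as.numeric(img), dim(img))
    list(values = vals, spacing = as.numeric(RNifti::pixdim(img))[1:3])
  } else if (grepl("\\.nrrd$", lp)) {
    .readNRRD(path)
  } else {
    stop("unsupported volume format: ", path,
         " (supported: .nii, .nii.gz, .nrrd)")
  }
}

#' @rdname readVolume
#' @export
writeVolume <- function(values, path, spacing = c(1, 1, 1)) {
  stopifnot(is.numeric(values), length(dim(values)) == 3L,
            length(spacing) == 3L, all(spacing > 0))
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    attr(values, "pixdim") <- as.numeric(spacing)
    img <- RNifti::asNifti(values, datatype = "double")
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.nrrd$", lp)) {
    .writeNRRD(values, path, spacing)
  } else {
    stop("unsupported volume format: ", path,
         " (supported: .nii, .nii.gz, .nrrd)")
  }
  invisible(path)
}

# Minimal NRRD0004 writer: raw little-endian doubles, 3-d, attached data.
.writeNRRD <- function(values, path, spacing) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    "# generated by DECTmaps",
    "type: double",
    "dimension: 3",
    paste("sizes:", paste(dim(values), collapse = " ")),
    paste("spacings:", paste(format(spacing, digits = 17), collapse = " ")),
    "endian: little",
    "encoding: raw",
    "")
  writeLines(hdr, con, sep = "\n")
  writeBin(as.numeric(values), con, size = 8, endian = "little")
}

.readNRRD <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!startsWith(magic, "NRRD"))
    stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated NRRD header")
    if (line == "") break
    if (startsWith(line, "#")) next
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(kv[2])]] <- kv[3]
  }
  type <- fields[["type"]]
  if (is.null(type) || !type %in% c("double", "float"))
    stop("unsupported NRRD type: ", type)
  if (!identical(fields[["encoding"]], "raw"))
    stop("unsupported NRRD encoding: ", fields[["encoding"]])
  sizes <- as.integer(strsplit(trimws(fields[["sizes"]]), "\\s+")[[1]])
  if (length(sizes) != 3L) stop("only 3-d NRRD volumes are supported")
  spacing <- if (!is.null(fields[["spacings"]]))
    as.numeric(strsplit(trimws(fields[["spacings"]]), "\\s+")[[1]])
  else c(1, 1, 1)
  size <- if (type == "double") 8L else 4L
  endian <- if (identical(fields[["endian"]], "big")) "big" else "little"
  vals <- readBin(con, "numeric", n = prod(sizes), size = size,
                  endian = endian)
  list(values = array(vals, sizes), spacing = spacing)
}

#' Render a colour-map overlay of a material map
#'
#' Writes a PNG of one axial slice: the base volume in grayscale with red
#' intensity proportional to the material-map HU, plus a vertical colour-bar
#' strip on the right whose top corresponds to the legend maximum.
#'
#' @param map a \code{\linkS4class{MaterialMap}}.
#' @param base a \code{\linkS4class{DualEnergyVolume}} (its 135-kVp volume
#'   is shown) or a 3-d array on the same grid.
#' @param slice axial (third-axis) slice index.
#' @param path output PNG path.
#' @param maxHU map HU mapped to full red; defaults to the map maximum
#'   (or 1 if the map is identically zero).
#' @param window HU window \code{c(lo, hi)} for the grayscale base.
#' @return \code{path}, invisibly, with attribute \code{legendMaxHU}.
#' @export
renderOverlay <- function(map, base, slice, path, maxHU = NULL,
                          window = NULL) {
  stopifnot(is(map, "MaterialMap"))
  baseVals <- .asValues(base)
  if (!identical(dim(baseVals), dim(map@values)))
    stop("map and base grids differ in shape")
  d <- dim(baseVals)
  if (slice < 1L || slice > d[3])
    stop("slice ", slice, " out of range 1..", d[3])
  b <- baseVals[, , slice]
  m <- map@values[, , slice]
  if (is.null(window)) window <- range(baseVals)
  if (diff(window) == 0) window[2] <- window[1] + 1
  g <- pmin(pmax((b - window[1]) / diff(window), 0), 1)
  if (is.null(maxHU)) maxHU <- max(map@values)
  if (maxHU <= 0) maxHU <- 1
  w <- pmin(m / maxHU, 1)
  # red overlay: push the red channel towards 1, damp green/blue
  red <- g + w * (1 - g)
  green <- g * (1 - w)
  blue <- g * (1 - w)
  # colour bar: right-hand strip, full red at the top (= maxHU in legend)
  barW <- max(2L, ceiling(d[1] / 16))
  wbar <- matrix(rep(seq(1, 0, length.out = d[1]), barW), ncol = barW)
  red <- cbind(red, matrix(0, d[1], 1), wbar)
  green <- cbind(green, matrix(0, d[1], 1), wbar * 0)
  blue <- cbind(blue, matrix(0, d[1], 1), wbar * 0)
  img <- array(c(red, green, blue), c(dim(red), 3L))
  png::writePNG(img, path)
  invisible(structure(path, legendMaxHU = maxHU))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(name, " stage: ", conditionMessage(e), call. = FALSE))
}

#' Run the full simulate-calibrate-decompose-analyze pipeline
#'
#' Demonstration pipeline tying all modules together on a phantom: builds
#' the phantom volume, writes both energy volumes (suffixes
#' \code{_80kvp}/\code{_135kvp}), calibrates the requested decomposition
#' bases from the bundled panel parameters, computes and writes the
#' material maps, places and artifact-screens ROIs in every ground-truth
#' region, and writes per-ROI summaries, structure contrasts, an overlay
#' image and a provenance record. Reruns with the same configuration and
#' seed produce identical CSV outputs.
#'
#' @param config named list or path to a YAML file with (all optional)
#'   entries \code{out_dir}, \code{seed}, \code{grid_shape},
#'   \code{noise_sd_low}, \code{noise_sd_high}, \code{materials} (subset of
#'   \code{"fluorine"}, \code{"calcium"}), \code{background_threshold},
#'   \code{artifact_max_fraction}, \code{n_rois}, \code{roi_size},
#'   \code{volume_format} (\code{"nii.gz"} or \code{"nrrd"}),
#'   \code{write_volumes}, \code{overlay_slice}.
#' @return Invisibly, a list with the output directory, the ROI summary
#'   table, the structure contrasts and the file manifest.
#' @examples
#' \donttest{
#' res <- runPipeline(list(out_dir = tempfile("dect"), seed = 7,
#'                         grid_shape = c(32, 32, 16)))
#' res$summaries[1:3, c("structure", "element", "report")]
#' }
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    out_dir = file.path(tempdir(), "dectmaps_run"),
    seed = 1L,
    grid_shape = c(48L, 48L, 24L),
    noise_sd_low = 542, noise_sd_high = 542,
    materials = c("fluorine", "calcium"),
    background_threshold = 100,
    artifact_max_fraction = 0.05,
    n_rois = 10L,
    roi_size = c(4L, 4L, 4L),
    volume_format = "nii.gz",
    write_volumes = TRUE,
    overlay_slice = NA
  ), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  ext <- match.arg(cfg$volume_format, c("nii.gz", "nrrd"))
  manifest <- character()
  vol <- .stage("simulate", {
    spec <- fossilBonePhantomSpec(gridShape = cfg$grid_shape,
                                  noiseSDLow = cfg$noise_sd_low,
                                  noiseSDHigh = cfg$noise_sd_high,
                                  seed = cfg$seed)
    buildPhantom(spec)
  })
  if (isTRUE(cfg$write_volumes)) {
    for (en in c("80kvp", "135kvp")) {
      f <- file.path(cfg$out_dir, sprintf("phantom_%s.%s", en, ext))
      writeVolume(if (en == "80kvp") lowEnergy(vol) else highEnergy(vol),
                  f, voxelSpacing(vol))
      manifest <- c(manifest, f)
    }
  }
  bases <- .stage("calibrate", {
    b <- list()
    if ("fluorine" %in% cfg$materials)
      b$fluorine <- buildFluorineBasis(
        backgroundThreshold = cfg$background_threshold)
    if ("calcium" %in% cfg$materials)
      b$calcium <- buildCalciumBasis(
        backgroundThreshold = cfg$background_threshold)
    for (nm in names(b)) {
      f <- file.path(cfg$out_dir, sprintf("basis_%s.json", nm))
      writeBasis(b[[nm]], f)
      manifest <- c(manifest, f)
    }
    b
  })
  maps <- .stage("decompose", {
    mp <- lapply(names(bases), function(nm) {
      m <- materialMap(vol, bases[[nm]], nm)
      f <- file.path(cfg$out_dir, sprintf("map_%s.%s", nm, ext))
      writeVolume(mapValues(m), f, voxelSpacing(m))
      manifest <<- c(manifest, f)
      m
    })
    names(mp) <- names(bases)
    mp
  })
  analysis <- .stage("analyze", {
    lab <- truthLabels(vol)
    regionNames <- vol@truth$regionLabels
    labels <- array(0L, dim(lab))
    roles <- list()
    clean <- if (is.null(artifactMask(vol))) array(FALSE, dim(lab))
             else artifactMask(vol)
    for (j in seq_along(regionNames)) {
      # ROIs go into artifact-free areas of each structure
      roiLab <- placeROIs(lab == j & !clean, n = cfg$n_rois,
                          size = cfg$roi_size,
                          codeOffset = (j - 1L) * cfg$n_rois)
      labels <- labels + roiLab
      roles[[j]] <- data.frame(
        code = (j - 1L) * cfg$n_rois + seq_len(cfg$n_rois),
        structure = regionNames[j], specimen = "phantom",
        age_ma = NA_real_, habitat = "synthetic", stringsAsFactors = FALSE)
    }
    rois <- roiSet(labels, do.call(rbind, roles), voxelSpacing(vol))
    if (!is.null(artifactMask(vol)))
      rois <- excludeArtifactROIs(rois, artifactMask(vol),
                                  cfg$artifact_max_fraction)
    summaries <- do.call(rbind, lapply(names(maps), function(nm) {
      s <- roiSummaries(maps[[nm]], rois)
      s$element <- nm
      s
    }))
    rownames(summaries) <- NULL
    f <- file.path(cfg$out_dir, "roi_summaries.csv")
    utils::write.csv(summaries, f, row.names = FALSE)
    manifest <- c(manifest, f)
    contrasts <- list()
    if (length(regionNames) >= 2L) {
      for (nm in names(maps)) {
        el <- summaries[summaries$element == nm & !summaries$excluded, ]
        contrasts[[nm]] <- anovaPosthoc(el$mean, el$structure)
      }
      rows <- do.call(rbind, lapply(names(contrasts), function(nm) {
        gc <- contrasts[[nm]]
        data.frame(element = nm, F = gc@F, p = gc@p,
                   df1 = gc@df[1], df2 = gc@df[2],
                   stringsAsFactors = FALSE)
      }))
      f <- file.path(cfg$out_dir, "contrasts.csv")
      utils::write.csv(rows, f, row.names = FALSE)
      manifest <- c(manifest, f)
    }
    list(rois = rois, summaries = summaries, contrasts = contrasts,
         manifest = manifest)
  })
  manifest <- analysis$manifest
  if (length(maps)) {
    slice <- cfg$overlay_slice
    if (is.na(slice)) slice <- ceiling(dim(lowEnergy(vol))[3] / 2)
    f <- file.path(cfg$out_dir, "overlay.png")
    .stage("render", renderOverlay(maps[[1]], vol, slice, f))
    manifest <- c(manifest, f)
  }
  report <- c(
    sprintf("DECTmaps pipeline (seed %d)", cfg$seed),
    sprintf("grid %s, noise SD %.0f/%.0f HU",
            paste(cfg$grid_shape, collapse = "x"),
            cfg$noise_sd_low, cfg$noise_sd_high),
    "",
    utils::capture.output(print(analysis$summaries[
      , c("code", "structure", "element", "report", "excluded")])))
  writeLines(report, file.path(cfg$out_dir, "report.txt"))
  prov <- cfg
  prov$package_version <- as.character(utils::packageVersion("DECTmaps"))
  yaml::write_yaml(prov, file.path(cfg$out_dir, "provenance.yaml"))
  manifest <- c(manifest, file.path(cfg$out_dir, c("report.txt",
                                                   "provenance.yaml")))
  invisible(list(out_dir = cfg$out_dir, summaries = analysis$summaries,
                 contrasts = analysis$contrasts, manifest = manifest))
}
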