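#' Construct an ROISet
#'
#' @param labels integer 3-d array of ROI codes (0 = outside).
#' @param roles data.frame with one row per code and columns \code{code},
#'   \code{structure}, \code{specimen}, \code{age_ma}, \code{habitat};
#'   \code{excluded}/\code{reason} columns are added if missing.
#' @param spacing numeric(3), mm per axis.
#' @return A validated \code{\linkS4class{ROISet}}.
#' @export
roiSet <- function(labels, roles, spacing = c(0.5, 0.5, 0.5)) {
  if (!is.integer(labels)) {
    stopifnot(all(labels == round(labels)))
    labels <- array(as.integer(labels), dim(labels))
  }
  if (is.null(roles$excluded)) roles$excluded <- FALSE
  if (is.null(roles$reason)) roles$reason <- ""
  new("ROISet", labels = labels, roles = roles, spacing = as.numeric(spacing))
}

#' Place non-overlapping box ROIs inside a region
#'
#' Deterministically tiles axis-aligned boxes of the given size over the
#' voxels where \code{mask} is TRUE, keeping only boxes fully inside the
#' mask, in column-major scan order, until \code{n} ROIs are placed. This
#' mimics the manual placement of several structure-specific ROIs in
#' representative areas of an object.
#'
#' @param mask logical 3-d array delimiting the structure.
#' @param n number of ROIs (default 10, the per-structure convention).
#' @param size integer(3), ROI box edge lengths in voxels.
#' @param gap gap in voxels between candidate boxes.
#' @param codeOffset added to the ROI codes (for combining structures).
#' @return Integer label array with codes \code{codeOffset + 1:n}.
#' @examples
#' m <- array(TRUE, c(20, 20, 10))
#' lab <- placeROIs(m, n = 10, size = c(4, 4, 4))
#' table(lab[lab > 0])
#' @export
placeROIs <- function(mask, n = 10L, size = c(4L, 4L, 4L), gap = 1L,
                      codeOffset = 0L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L, all(size >= 1L))
  d <- dim(mask)
  if (!any(mask)) stop("empty mask")
  step <- size + gap
  # tile from the mask's bounding box so boxes align with the structure
  idx <- which(mask, arr.ind = TRUE)
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  starts <- lapply(1:3, function(k) {
    if (hi[k] - size[k] + 1L < lo[k]) integer() else
      seq.int(lo[k], hi[k] - size[k] + 1L, step[k])
  })
  labels <- array(0L, d)
  placed <- 0L
  for (z in starts[[3]]) for (y in starts[[2]]) for (x in starts[[1]]) {
    if (placed >= n) break
    xs <- x:(x + size[1] - 1L)
    ys <- y:(y + size[2] - 1L)
    zs <- z:(z + size[3] - 1L)
    if (all(mask[xs, ys, zs])) {
      placed <- placed + 1L
      labels[xs, ys, zs] <- codeOffset + placed
    }
  }
  if (placed < n)
    stop("could only place ", placed, " of ", n, " ROIs inside the mask")
  labels
}

.asValues <- function(map) {
  if (is(map, "MaterialMap")) map@values
  else if (is(map, "DualEnergyVolume")) map@high
  else map
}

#' Descriptive statistics of one ROI
#'
#' Computes mean, sample (n - 1) SD, median (midpoint of the central pair
#' for even counts) and range over the ROI voxels of a material map or HU
#' volume.
#'
#' @param map a \code{\linkS4class{MaterialMap}}, a
#'   \code{\linkS4class{DualEnergyVolume}} (its 135-kVp volume is used), or
#'   a numeric array.
#' @param roi logical mask, integer voxel indices, or a bare numeric vector
#'   of the ROI values themselves.
#' @return An \code{\linkS4class{ROISummary}}.
#' @examples
#' summarizeROI(array(c(1, 2, 3, 4), c(4, 1, 1)), rep(TRUE, 4))
#' @export
summarizeROI <- function(map, roi) {
  vals <- .asValues(map)
  v <- if (missing(roi)) as.vector(vals)
       else if (is.logical(roi)) vals[roi]
       else if (is.numeric(roi) && is.null(dim(vals))) roi
       else vals[roi]
  v <- as.vector(v)
  if (length(v) == 0L) stop("empty ROI")
  new("ROISummary",
      mean = mean(v),
      sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
      median = stats::median(v),
      min = min(v), max = max(v),
      nVoxels = length(v))
}

#' Format an ROI summary for reporting
#'
#' Renders the conventional "mean +/- SD HU; median, min-max HU" report
#' string, rounded to integer HU.
#'
#' @param x an \code{\linkS4class{ROISummary}}.
#' @return character(1), e.g. \code{"1 ± 4 HU; 0, 0–14 HU"}.
#' @export
formatROISummary <- function(x) {
  stopifnot(is(x, "ROISummary"))
  sprintf("%.0f ± %.0f HU; %.0f, %.0f–%.0f HU",
          x@mean, if (is.na(x@sd)) 0 else x@sd, x@median, x@min, x@max)
}

#' Summaries of every ROI in an ROISet
#'
#' @param map values to summarise (see \code{\link{summarizeROI}}).
#' @param rois an \code{\linkS4class{ROISet}} aligned with the map grid.
#' @param includeExcluded keep excluded ROIs in the table (flagged) rather
#'   than dropping them.
#' @return data.frame with one row per ROI: the role columns plus
#'   \code{mean}, \code{sd}, \code{median}, \code{min}, \code{max},
#'   \code{n_voxels}, \code{report}.
#' @export
roiSummaries <- function(map, rois, includeExcluded = TRUE) {
  stopifnot(is(rois, "ROISet"))
  vals <- .asValues(map)
  if (!identical(dim(vals), dim(rois@labels)))
    stop("map and ROI label grids differ in shape")
  roles <- rois@roles
  rows <- lapply(seq_len(nrow(roles)), function(i) {
    code <- roles$code[i]
    s <- summarizeROI(vals, rois@labels == code)
    cbind(roles[i, , drop = FALSE],
          data.frame(mean = s@mean, sd = s@sd, median = s@median,
                     min = s@min, max = s@max, n_voxels = s@nVoxels,
                     report = formatROISummary(s),
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!includeExcluded) out <- out[!out$excluded, , drop = FALSE]
  out
}

#' Flag ROIs contaminated by surface artifacts
#'
#' ROIs whose fraction of artifact-flagged voxels strictly exceeds
#' \code{maxFraction} are marked excluded with a reason; all others are
#' retained. Mirrors the practice of analysing only ROIs placed in
#' artifact-free areas.
#'
#' @param rois an \code{\linkS4class{ROISet}}.
#' @param artifactMask logical array aligned with the ROI grid.
#' @param maxFraction tolerated artifact-voxel fraction (default 0.05).
#' @return The \code{ROISet} with updated \code{excluded}/\code{reason}.
#' @export
excludeArtifactROIs <- function(rois, artifactMask, maxFraction = 0.05) {
  stopifnot(is(rois, "ROISet"), is.logical(artifactMask),
            maxFraction >= 0, maxFraction <= 1)
  if (!identical(dim(artifactMask), dim(rois@labels)))
    stop("artifact mask and ROI label grids differ in shape")
  roles <- rois@roles
  for (i in seq_len(nrow(roles))) {
    sel <- rois@labels == roles$code[i]
    frac <- sum(artifactMask[sel]) / sum(sel)
    if (frac > maxFraction) {
      roles$excluded[i] <- TRUE
      roles$reason[i] <- sprintf("artifact fraction %.3f > %.3f",
                                 frac, maxFraction)
    }
  }
  rois@roles <- roles
  rois
}

#' One-way ANOVA with Bonferroni and Tukey HSD post-hoc tests
#'
#' Classical (equal-variance) parametric one-way ANOVA, followed by
#' pairwise pooled-variance t tests with Bonferroni adjustment
#' (p_adj = min(1, m * p_raw) over the m pairs) and Tukey HSD via the
#' studentized-range distribution. With two groups the ANOVA F equals the
#' square of the pooled two-sample t statistic. If all observations are
#' identical across groups, F = 0 and p = 1 by convention.
#'
#' @param values numeric vector of observations (here typically ROI means,
#'   the unit of analysis).
#' @param groups group labels, same length as \code{values}.
#' @param alpha two-sided significance level (default 0.05).
#' @param posthoc compute the pairwise table (set \code{FALSE} to skip, e.g.
#'   in large simulations).
#' @return A \code{\linkS4class{GroupComparison}}.
#' @examples
#' set.seed(1)
#' anovaPosthoc(c(rnorm(10), rnorm(10, 3)), rep(c("a", "b"), each = 10))
#' @export
anovaPosthoc <- function(values, groups, alpha = 0.05, posthoc = TRUE) {
  stopifnot(length(values) == length(groups))
  groups <- factor(groups)
  if (nlevels(groups) < 2L)
    stop("at least two groups are required")
  n <- as.integer(table(groups))
  if (any(n < 2L))
    stop("every group needs at least two observations")
  lev <- levels(groups)
  k <- nlevels(groups)
  N <- length(values)
  df <- c(k - 1, N - k)
  gm <- tapply(values, groups, mean)
  sse <- sum((values - gm[groups])^2)
  ssb <- sum(n * (gm - mean(values))^2)
  degenerate <- sse == 0
  if (degenerate) {
    # zero residual variance: conventionally F = 0, p = 1 when the group
    # means coincide too, otherwise perfect separation
    if (ssb == 0) { Fstat <- 0; p <- 1 } else { Fstat <- Inf; p <- 0 }
  } else {
    ow <- stats::oneway.test(values ~ groups, var.equal = TRUE)
    Fstat <- unname(ow$statistic)
    p <- unname(ow$p.value)
  }
  pw <- data.frame(group1 = character(), group2 = character(),
                   diff = numeric(), p_raw = numeric(),
                   p_bonferroni = numeric(), p_tukey = numeric(),
                   significant = logical(), stringsAsFactors = FALSE)
  if (posthoc) {
    pairs <- utils::combn(seq_len(k), 2)
    m <- ncol(pairs)
    if (!degenerate) {
      praw_mat <- stats::pairwise.t.test(values, groups,
                                         p.adjust.method = "none",
                                         pool.sd = TRUE)$p.value
      tk <- stats::TukeyHSD(stats::aov(values ~ groups))$groups
    }
    rows <- vector("list", m)
    for (j in seq_len(m)) {
      a <- pairs[1, j]; b <- pairs[2, j]
      diffab <- unname(gm[b] - gm[a])
      if (degenerate) {
        praw <- if (diffab == 0) 1 else 0
        ptk <- praw
      } else {
        praw <- praw_mat[lev[b], lev[a]]
        ptk <- unname(tk[paste0(lev[b], "-", lev[a]), "p adj"])
      }
      rows[[j]] <- data.frame(
        group1 = lev[a], group2 = lev[b], diff = diffab,
        p_raw = praw, p_bonferroni = min(1, m * praw), p_tukey = ptk,
        stringsAsFactors = FALSE)
    }
    pw <- do.call(rbind, rows)
    pw$significant <- pw$p_bonferroni < alpha
  }
  new("GroupComparison", groups = lev, n = n, F = Fstat, p = p,
      df = df, pairwise = pw, alpha = alpha)
}

#' Per-specimen structure contrasts (bone vs sediment, healthy vs diseased)
#'
#' For every specimen with at least two structures, runs the one-way
#' ANOVA/post-hoc comparison of ROI means between structures. Specimens
#' with a single structure are skipped with a warning.
#'
#' @param summaries data.frame of ROI-level values with columns
#'   \code{specimen}, \code{structure} and \code{mean} (one row per ROI),
#'   e.g. from \code{\link{roiSummaries}} or \code{\link{simulateCohort}};
#'   excluded ROIs (column \code{excluded}) are dropped.
#' @param alpha two-sided significance level.
#' @return Named list of \code{\linkS4class{GroupComparison}}, one per
#'   comparable specimen.
#' @export
contrastStructures <- function(summaries, alpha = 0.05) {
  need <- c("specimen", "structure", "mean")
  stopifnot(all(need %in% names(summaries)))
  if (!is.null(summaries$excluded))
    summaries <- summaries[!summaries$excluded, , drop = FALSE]
  out <- list()
  for (sp in unique(summaries$specimen)) {
    d <- summaries[summaries$specimen == sp, , drop = FALSE]
    if (length(unique(d$structure)) < 2L) {
      warning("specimen '", sp, "': only one structure present, skipped")
      next
    }
    out[[sp]] <- anovaPosthoc(d$mean, d$structure, alpha = alpha)
  }
  out
}

#' Fluorine age trend across terrestrial specimens
#'
#' Orders specimens by geological age, reports whether the terrestrial
#' per-specimen fluorine means are monotone non-decreasing with age (with
#' the violating pair identified if not), and runs the cross-specimen
#' ANOVA/post-hoc comparison on the terrestrial ROI means.
#'
#' @param summaries data.frame of ROI-level values with columns
#'   \code{specimen}, \code{age_ma}, \code{habitat}, \code{mean}; excluded
#'   ROIs are dropped if an \code{excluded} column is present.
#' @param alpha two-sided significance level for the post-hoc comparison.
#' @return List with \code{specimens} (data.frame sorted by age with
#'   per-specimen means), \code{monotone} (logical), \code{violations}
#'   (data.frame of violating adjacent pairs) and \code{posthoc}
#'   (\code{\linkS4class{GroupComparison}} across terrestrial specimens, or
#'   \code{NULL} if fewer than two).
#' @export
ageTrend <- function(summaries, alpha = 0.05) {
  need <- c("specimen", "age_ma", "habitat", "mean")
  stopifnot(all(need %in% names(summaries)))
  if (!is.null(summaries$excluded))
    summaries <- summaries[!summaries$excluded, , drop = FALSE]
  terr <- summaries[summaries$habitat == "terrestrial", , drop = FALSE]
  if (length(unique(terr$specimen)) < 2L)
    stop("at least two terrestrial specimens are required")
  agg <- stats::aggregate(mean ~ specimen + age_ma, data = terr, FUN = mean)
  agg <- agg[order(agg$age_ma), , drop = FALSE]
  rownames(agg) <- NULL
  # monotone non-decreasing with age, over all strictly age-ordered pairs
  # (specimens of equal age impose no ordering on each other)
  viol <- list()
  for (i in seq_len(nrow(agg) - 1L)) for (j in (i + 1L):nrow(agg)) {
    if (agg$age_ma[j] > agg$age_ma[i] && agg$mean[j] < agg$mean[i])
      viol[[length(viol) + 1L]] <- data.frame(
        younger = agg$specimen[i], older = agg$specimen[j],
        younger_mean = agg$mean[i], older_mean = agg$mean[j],
        stringsAsFactors = FALSE)
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(younger = character(), older = character(),
               younger_mean = numeric(), older_mean = numeric(),
               stringsAsFactors = FALSE)
  posthoc <- if (length(unique(terr$specimen)) >= 2L &&
                 all(table(terr$specimen) >= 2L))
    anovaPosthoc(terr$mean, terr$specimen, alpha = alpha) else NULL
  list(specimens = agg, monotone = length(viol) == 0L,
       violations = violations, posthoc = posthoc)
}

#' Simulate the synthetic fossil cohort and quantify its material maps
#'
#' End-to-end cohort experiment: builds each specimen phantom from
#' \code{\link{fossilCohortSpecs}}, computes calcium and fluorine material
#' maps with the default bases, places 10 box ROIs per structure inside the
#' ground-truth regions (eroded by the artifact band, if any), screens them
#' against the artifact mask, and returns per-ROI summaries.
#'
#' @param seed base seed forwarded to \code{\link{fossilCohortSpecs}}.
#' @param noiseSD voxel noise SD in HU per energy.
#' @param nROIs ROIs per structure.
#' @param roiSize integer(3) ROI box size in voxels.
#' @return data.frame with one row per specimen x structure x element x ROI:
#'   columns \code{specimen}, \code{structure}, \code{age_ma},
#'   \code{habitat}, \code{element}, \code{code}, \code{excluded},
#'   \code{reason}, \code{mean}, \code{sd}, \code{median}, \code{min},
#'   \code{max}, \code{n_voxels}, \code{report}.
#' @examples
#' \donttest{
#' coh <- simulateCohort(seed = 1)
#' aggregate(mean ~ specimen + element, coh[coh$structure == "bone", ], mean)
#' }
#' @export
simulateCohort <- function(seed = 1L, noiseSD = 10, nROIs = 10L,
                           roiSize = c(4L, 4L, 4L)) {
  specs <- fossilCohortSpecs(noiseSD = noiseSD, seed = seed)
  fBasis <- buildFluorineBasis()
  caBasis <- buildCalciumBasis()
  out <- list()
  for (nm in names(specs)) {
    entry <- specs[[nm]]
    vol <- buildPhantom(entry$spec)
    lab <- truthLabels(vol)
    clean <- if (is.null(artifactMask(vol))) array(FALSE, dim(lab))
             else artifactMask(vol)
    labels <- array(0L, dim(lab))
    roles <- list()
    for (j in seq_along(entry$structures)) {
      roiLab <- placeROIs(lab == j & !clean, n = nROIs, size = roiSize,
                          codeOffset = (j - 1L) * nROIs)
      labels <- labels + roiLab
      roles[[j]] <- data.frame(
        code = (j - 1L) * nROIs + seq_len(nROIs),
        structure = entry$structures[j], specimen = nm,
        age_ma = entry$age_ma, habitat = entry$habitat,
        stringsAsFactors = FALSE)
    }
    rois <- roiSet(labels, do.call(rbind, roles), voxelSpacing(vol))
    if (!is.null(artifactMask(vol)))
      rois <- excludeArtifactROIs(rois, artifactMask(vol))
    for (el in c("fluorine", "calcium")) {
      mp <- materialMap(vol, if (el == "fluorine") fBasis else caBasis, el)
      sm <- roiSummaries(mp, rois)
      sm$element <- el
      out[[paste(nm, el)]] <- sm
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
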