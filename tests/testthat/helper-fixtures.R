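# Shared fixtures and independent oracles for the test suite.

# Gradients of the default fluorine basis, written out independently of the
# package's basis constructor.
G_F <- 0.69
G_CA <- 3000 / 4248
G_FE <- 7365 / 10000

# A small two-region phantom: calcite block beside a halite block.
tinyTwoRegionSpec <- function(noiseLow = 0, noiseHigh = 0, seed = 1L,
                              bandWidth = 0, offsetHU = 0) {
  phantomSpec(
    c(14L, 10L, 8L),
    list(
      regionBox("a", c(2, 2, 2), c(6, 9, 7), c(calcite = 1)),
      regionBox("b", c(9, 2, 2), c(13, 9, 7),
                c(halite = 0.5, background = 0.5))
    ),
    noiseSDLow = noiseLow, noiseSDHigh = noiseHigh,
    artifactBandWidth = bandWidth, artifactOffsetHU = offsetHU,
    seed = seed)
}

# Brute-force city-block distance from each voxel to the nearest background
# voxel, treating everything outside the grid as background. O(n^2) over a
# padded grid; only for small fixtures.
bruteForceBandMask <- function(object, bandWidth) {
  d <- dim(object)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- object
  bgIdx <- which(!pad, arr.ind = TRUE)
  mask <- array(FALSE, d)
  objIdx <- which(pad, arr.ind = TRUE)
  for (r in seq_len(nrow(objIdx))) {
    v <- objIdx[r, ]
    dmin <- min(abs(bgIdx[, 1] - v[1]) + abs(bgIdx[, 2] - v[2]) +
                abs(bgIdx[, 3] - v[3]))
    if (dmin <= bandWidth)
      mask[v[1] - 1L, v[2] - 1L, v[3] - 1L] <- TRUE
  }
  mask
}

# Scalar reference implementation of the three-material rule, written
# independently of the vectorised package core.
referenceDecompose <- function(huLow, huHigh, g, threshold = 100) {
  if (huLow <= threshold) return(c(0, 0, 0))
  q <- huHigh / huLow
  m <- c(0, 0, 0)
  if (q <= g[1]) {
    m[1] <- huLow * g[1]
  } else if (q < g[2]) {
    c2 <- (huHigh - g[1] * huLow) / (g[2] - g[1])
    c1 <- huLow - c2
    m[1] <- c1 * g[1]; m[2] <- c2 * g[2]
  } else if (q < g[3]) {
    c3 <- (huHigh - g[2] * huLow) / (g[3] - g[2])
    c2 <- huLow - c3
    m[2] <- c2 * g[2]; m[3] <- c3 * g[3]
  } else {
    m[3] <- huLow * g[3]
  }
  pmax(m, 0)
}
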