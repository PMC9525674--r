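test_that("forward model mixes HU linearly in volume fractions", {
  expect_equal(forwardHU(c(calcite = 1)),
               c(hu_low = 4248, hu_high = 3000))
  expect_equal(forwardHU(c(calcite = 0.5, background = 0.5)),
               c(hu_low = 2124, hu_high = 1500))
  expect_equal(forwardHU(c(background = 1)), c(hu_low = 0, hu_high = 0))
  expect_error(forwardHU(c(kryptonite = 1)), "unknown material")
  expect_error(forwardHU(c(calcite = 0.6, background = 0.5)), "sum to 1")
  expect_error(forwardHU(c(calcite = 1.5, background = -0.5)), ">= 0")
})

test_that("noiseless phantom voxels equal the forward model exactly", {
  vol <- buildPhantom(tinyTwoRegionSpec())
  lab <- truthLabels(vol)
  huA <- forwardHU(c(calcite = 1))
  huB <- forwardHU(c(halite = 0.5, background = 0.5))
  expect_true(all(lowEnergy(vol)[lab == 1L] == huA[1]))
  expect_true(all(highEnergy(vol)[lab == 1L] == huA[2]))
  expect_true(all(lowEnergy(vol)[lab == 2L] == huB[1]))
  expect_true(all(highEnergy(vol)[lab == 2L] == huB[2]))
  # uncovered voxels are background at exactly 0 HU
  expect_true(all(lowEnergy(vol)[lab == 0L] == 0))
  expect_true(all(highEnergy(vol)[lab == 0L] == 0))
  # region volume fractions sum to 1 everywhere
  for (comp in truthCompositions(vol))
    expect_equal(sum(comp), 1)
})

test_that("overlapping regions are rejected", {
  sp <- phantomSpec(c(10, 10, 10),
                    list(regionBox("a", c(2, 2, 2), c(6, 6, 6),
                                   c(calcite = 1)),
                         regionSphere("b", c(6, 6, 6), 2, c(halite = 1))))
  expect_error(buildPhantom(sp), "overlaps")
})

test_that("phantom noise is seeded, independent per energy, reproducible", {
  v7a <- buildPhantom(tinyTwoRegionSpec(noiseLow = 30, noiseHigh = 20,
                                        seed = 7L))
  v7b <- buildPhantom(tinyTwoRegionSpec(noiseLow = 30, noiseHigh = 20,
                                        seed = 7L))
  v8 <- buildPhantom(tinyTwoRegionSpec(noiseLow = 30, noiseHigh = 20,
                                       seed = 8L))
  expect_identical(lowEnergy(v7a), lowEnergy(v7b))
  expect_identical(highEnergy(v7a), highEnergy(v7b))
  expect_false(identical(lowEnergy(v7a), lowEnergy(v8)))
  # the two energy volumes carry different (independent) noise draws
  noiseLow <- lowEnergy(v7a) - lowEnergy(buildPhantom(tinyTwoRegionSpec()))
  noiseHigh <- highEnergy(v7a) - highEnergy(buildPhantom(tinyTwoRegionSpec()))
  expect_lt(abs(cor(as.vector(noiseLow), as.vector(noiseHigh))), 0.05)
})

test_that("noisy voxel statistics converge to the specified moments", {
  sp <- phantomSpec(c(50L, 50L, 40L),
                    list(regionBox("all", c(1, 1, 1), c(50, 50, 40),
                                   c(calcite = 1))),
                    noiseSDLow = 80, noiseSDHigh = 60, seed = 11L)
  vol <- buildPhantom(sp)
  n <- 50 * 50 * 40
  x <- as.vector(highEnergy(vol))
  expect_lt(abs(mean(x) - 3000), 3 * 60 / sqrt(n))
  expect_lt(abs(sd(x) - 60), 3 * 60 / sqrt(2 * n))
  y <- as.vector(lowEnergy(vol))
  expect_lt(abs(mean(y) - 4248), 3 * 80 / sqrt(n))
  expect_lt(abs(sd(y) - 80), 3 * 80 / sqrt(2 * n))
})

test_that("default fossil-bone phantom emulates heavily mineralized bone", {
  vol <- buildPhantom(fossilBonePhantomSpec(seed = 3L))
  lab <- truthLabels(vol)
  interior <- lab == 1L & !artifactMask(vol)
  x <- highEnergy(vol)[interior]
  n <- length(x)
  expect_gt(n, 1000)
  expect_lt(abs(mean(x) - 3040), 3 * 542 / sqrt(n))
  expect_lt(abs(sd(x) - 542), 3 * 542 / sqrt(2 * n))
})

test_that("surface artifact band matches a brute-force distance oracle", {
  sp <- phantomSpec(c(11L, 11L, 9L),
                    list(regionSphere("s", c(6, 6, 5), 3.5,
                                      c(calcite = 1))))
  vol <- buildPhantom(sp)
  object <- truthLabels(vol) > 0L
  for (w in c(1L, 2L)) {
    shifted <- addSurfaceArtifact(vol, w, 500)
    oracle <- bruteForceBandMask(object, w)
    expect_identical(artifactMask(shifted), oracle)
    # offset applied inside the band, both energies; interior untouched
    expect_equal(lowEnergy(shifted)[oracle],
                 lowEnergy(vol)[oracle] + 500)
    expect_equal(highEnergy(shifted)[oracle],
                 highEnergy(vol)[oracle] + 500)
    inside <- object & !oracle
    expect_identical(highEnergy(shifted)[inside], highEnergy(vol)[inside])
    expect_identical(lowEnergy(shifted)[!object], lowEnergy(vol)[!object])
  }
  # zero band width is a no-op with an empty mask
  same <- addSurfaceArtifact(vol, 0, 500)
  expect_identical(highEnergy(same), highEnergy(vol))
  expect_false(any(artifactMask(same)))
})

test_that("phantom HU values stay inside the scanner measurement range", {
  sp <- phantomSpec(c(8, 8, 8),
                    list(regionBox("fe", c(2, 2, 2), c(7, 7, 7),
                                   c(iron = 1))),
                    artifactBandWidth = 1, artifactOffsetHU = 20000)
  vol <- buildPhantom(sp)
  expect_lte(max(lowEnergy(vol)), 32767)
  expect_equal(max(lowEnergy(vol)), 32767)  # clamped, not overflowed
})

test_that("mixtureForQuotient places a mixture at a target quotient", {
  s <- materialSignatures()
  fa <- unlist(s[s$material == "fluorapatite", c("hu_low", "hu_high")])
  ca <- unlist(s[s$material == "calcite", c("hu_low", "hu_high")])
  q <- (G_F + G_CA) / 2
  a <- mixtureForQuotient(fa, ca, q)
  hu <- forwardHU(c(fluorapatite = a, calcite = 1 - a))
  expect_equal(unname(hu[2] / hu[1]), q, tolerance = 1e-12)
  expect_error(mixtureForQuotient(fa, ca, 0.9), "not spanned")
})
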