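basis <- buildFluorineBasis()

test_that("voxel quotient reproduces material quotients and background", {
  expect_equal(voxelQuotient(5432, 3753), 3753 / 5432)
  expect_equal(voxelQuotient(4248, 3000), 3000 / 4248)
  expect_true(is.na(voxelQuotient(50, 40)))
  expect_true(is.na(voxelQuotient(100, 80)))   # threshold is inclusive
  q <- voxelQuotient(array(c(50, 200), c(2, 1, 1)),
                     array(c(40, 150), c(2, 1, 1)))
  expect_identical(dim(q), c(2L, 1L, 1L))
  expect_equal(as.vector(q), c(NA, 0.75))
})

test_that("pure anchor and background voxels decompose trivially", {
  onCalcium <- decomposeVoxel(4248, 3000, basis)
  expect_equal(unname(onCalcium$maps),
               c(0, 3000, 0))  # all signal on the calcium direction
  bg <- decomposeVoxel(0, 0, basis)
  expect_true(bg$background)
  expect_equal(unname(bg$maps), c(0, 0, 0))
})

test_that("a fluorite-like voxel splits into fluorine and calcium exactly", {
  r <- decomposeVoxel(5432, 3753, basis)
  # frozen from the exact 2x2 solve with g_F = 0.69, g_Ca = 3000/4248:
  # c_Ca = (3753 - 0.69 * 5432) / (g_Ca - 0.69), c_F = 5432 - c_Ca
  cCa <- (3753 - 0.69 * 5432) / (G_CA - 0.69)
  cF <- 5432 - cCa
  expect_equal(unname(r$maps["fluorine"]), cF * 0.69)
  expect_equal(unname(r$maps["fluorine"]), 3538.714286, tolerance = 1e-9)
  expect_equal(unname(r$maps["calcium"]), 3753 - cF * 0.69)
  expect_equal(unname(r$magnitudes["fluorine"] + r$magnitudes["calcium"]),
               5432)  # 80-kVp conservation
  expect_equal(unname(r$maps["iron"]), 0)
})

test_that("bracketed decomposition conserves 80-kVp signal and round-trips", {
  set.seed(101)
  g <- unname(gradients(basis))
  for (pair in list(c(1, 2), c(2, 3))) {
    n <- 500
    cA <- runif(n, 0, 4000)
    cB <- runif(n, 0, 4000)
    L <- cA + cB
    H <- cA * g[pair[1]] + cB * g[pair[2]]
    keep <- L > backgroundThreshold(basis)
    r <- DECTmaps:::.decomposeHU(L[keep], H[keep], basis)
    expect_equal(rowSums(r$magnitudes), L[keep], tolerance = 1e-12)
    expect_equal(r$magnitudes[, pair[1]], cA[keep], tolerance = 1e-9)
    expect_equal(r$magnitudes[, pair[2]], cB[keep], tolerance = 1e-9)
    other <- setdiff(1:3, pair)
    expect_true(all(r$maps[, other] == 0))
  }
})

test_that("fluorine map is zero at and beyond the calcium gradient", {
  set.seed(7)
  L <- runif(2000, 200, 6000)
  q <- runif(2000, G_CA, 1.2)
  r <- DECTmaps:::.decomposeHU(L, L * q, basis)
  expect_true(all(r$maps[, "fluorine"] == 0))
})

test_that("fluorine map decreases strictly in the quotient inside its bracket", {
  L <- 4000
  qs <- seq(G_F + 1e-6, G_CA - 1e-6, length.out = 50)
  f <- vapply(qs, function(q)
    decomposeVoxel(L, L * q, basis)$maps[["fluorine"]], 0)
  expect_true(all(diff(f) < 0))
})

test_that("material maps are voxelwise, deterministic and metadata-preserving", {
  sp <- phantomSpec(c(10, 8, 6),
                    list(regionBox("f", c(2, 2, 2), c(9, 7, 5),
                                   c(fluorite = 1))),
                    voxelSpacing = c(0.5, 0.5, 0.3))
  vol <- buildPhantom(sp)
  fm <- materialMap(vol, basis, "fluorine")
  expect_identical(dim(mapValues(fm)), dim(lowEnergy(vol)))
  expect_equal(voxelSpacing(fm), c(0.5, 0.5, 0.3))
  inside <- truthLabels(vol) == 1L
  single <- decomposeVoxel(5432, 3753, basis)$maps[["fluorine"]]
  expect_true(all(mapValues(fm)[inside] == single))
  expect_true(all(mapValues(fm)[!inside] == 0))
  expect_identical(mapValues(materialMap(vol, basis, "fluorine")),
                   mapValues(fm))
  # a constant calcium-anchor volume has an identically zero fluorine map
  spCa <- phantomSpec(c(6, 6, 6),
                      list(regionBox("c", c(1, 1, 1), c(6, 6, 6),
                                     c(calcite = 1))))
  expect_true(all(mapValues(materialMap(buildPhantom(spCa), basis,
                                        "fluorine")) == 0))
  expect_error(materialMap(vol, basis, "unobtainium"), "not in basis")
})

test_that("decomposition is linear on the bracketed fluorine segment", {
  # voxels built as alpha * calcium-anchor + beta * pure-fluorine vector
  # recover exactly beta's fluorine contribution
  set.seed(21)
  for (i in 1:20) {
    alpha <- runif(1, 0.1, 1.5)
    beta <- runif(1, 0.1, 1.5)
    L <- alpha * 4248 + beta * 1000
    H <- alpha * 3000 + beta * 1000 * 0.69
    r <- decomposeVoxel(L, H, basis)
    expect_equal(unname(r$maps["fluorine"]), beta * 1000 * 0.69,
                 tolerance = 1e-9)
    expect_equal(unname(r$maps["calcium"]), alpha * 3000, tolerance = 1e-9)
  }
})

test_that("mean map under noise agrees with an independent Monte-Carlo oracle", {
  L0 <- 4500; H0 <- 3150; sdN <- 60; n <- 1e4
  g <- unname(gradients(basis))
  set.seed(31)
  r <- DECTmaps:::.decomposeHU(L0 + rnorm(n, 0, sdN), H0 + rnorm(n, 0, sdN),
                               basis)
  implMean <- mean(r$maps[, "fluorine"])
  set.seed(32)  # independent replicate through the scalar reference rule
  oracle <- vapply(seq_len(n), function(i)
    referenceDecompose(L0 + rnorm(1, 0, sdN), H0 + rnorm(1, 0, sdN), g)[1], 0)
  se <- sqrt(var(r$maps[, "fluorine"]) / n + var(oracle) / n)
  expect_lt(abs(implMean - mean(oracle)), 3 * se)
})
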