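test_that("dual-energy quotients reproduce the panel's printed values", {
  expect_equal(computeQuotient(5432, 3753), 0.691)   # fluorite
  expect_equal(computeQuotient(3196, 2153), 0.674)   # sulfur
  expect_equal(computeQuotient(1569, 939), 0.598)    # sodium chloride
  expect_equal(computeQuotient(24422, 18311, 2), 0.75)  # iron rod
  # calcite computes to 0.706 at 3 decimals (the table's 0.707 is a
  # documented one-ulp irregularity of the printed value)
  expect_equal(computeQuotient(4248, 3000), 0.706)
  expect_equal(computeQuotient(123, 123), 1)
  expect_equal(computeQuotient(5432, 3753, NULL), 3753 / 5432)
  expect_error(computeQuotient(0, 100), "undefined")
})

test_that("ingesting measurements preserves order and validates input", {
  cal <- ingestMeasurements(calibrationPanel())
  expect_identical(cal$material, calibrationPanel()$material)
  q <- setNames(cal$quotient, cal$material)
  expect_equal(unname(q[c("fluorite", "sulfur", "sodium_chloride")]),
               c(0.691, 0.674, 0.598))
  expect_equal(cal$quotient_full, cal$hu_high / cal$hu_low)

  expect_error(ingestMeasurements(data.frame()), "non-empty")
  dup <- rbind(calibrationPanel(), calibrationPanel()[1, ])
  expect_error(ingestMeasurements(dup), "duplicate")

  # round-trips through CSV
  f <- tempfile(fileext = ".csv")
  write.csv(calibrationPanel(), f, row.names = FALSE)
  expect_equal(ingestMeasurements(f)$quotient, cal$quotient)

  # a non-positive hu_low carries no quotient
  odd <- data.frame(material = "air", hu_low = -1000, hu_high = -1000)
  expect_true(is.na(ingestMeasurements(odd)$quotient))
})

test_that("default bases have the documented sorted gradient geometry", {
  fb <- buildFluorineBasis()
  expect_identical(basisMaterials(fb), c("fluorine", "calcium", "iron"))
  expect_equal(unname(gradients(fb)), c(0.69, 3000 / 4248, 7365 / 10000),
               tolerance = 1e-12)
  expect_false(is.unsorted(gradients(fb), strictly = TRUE))
  # the default fluorine gradient is the fluorite quotient at 2 decimals
  expect_equal(round(computeQuotient(5432, 3753, NULL), 2),
               unname(gradients(fb)["fluorine"]))

  cb <- buildCalciumBasis()
  expect_identical(basisMaterials(cb), c("calcium", "iron", "soft_tissue"))
  expect_equal(unname(gradients(cb)),
               c(3000 / 4248, 18311 / 24422, 1), tolerance = 1e-12)
  # anchors reproduce their gradients
  a <- anchors(fb)["calcium", ]
  expect_equal(unname(a["hu_high"] / a["hu_low"]),
               unname(gradients(fb)["calcium"]))
})

test_that("degenerate and invalid basis parameters are rejected", {
  expect_error(buildFluorineBasis(fluorineGradient = 3000 / 4248),
               "degenerate")
  expect_error(buildFluorineBasis(fluorineGradient = 2.5), "0, 2")
  expect_error(buildFluorineBasis(calciumAnchor = c(-10, 3000)), "positive")
  expect_error(buildCalciumBasis(softTissueGradient = 18311 / 24422),
               "degenerate")
})

test_that("basis JSON serialization round-trips exactly", {
  f <- tempfile(fileext = ".json")
  fb <- buildFluorineBasis(backgroundThreshold = 80)
  writeBasis(fb, f)
  fb2 <- readBasis(f)
  expect_equal(gradients(fb2), gradients(fb))
  expect_equal(anchors(fb2), anchors(fb))
  expect_equal(backgroundThreshold(fb2), 80)
})

test_that("effective atomic number follows the power-law electron mean", {
  # a single element is a fixed point at any exponent
  expect_equal(effectiveZ(c(Fe = 1)), 26)
  expect_equal(effectiveZ(c(Fe = 2), exponent = 1.5), 26)
  # water, direct evaluation of the closed form
  expect_equal(effectiveZ(c(H = 2, O = 1)), 7.41667226, tolerance = 1e-7)
  # calcite: equals the closed form (which differs from the panel's
  # chemist-supplied 15.88; z_eff is informational only)
  w <- c(Ca = 20, C = 6, O = 8 * 3) / (20 + 6 + 24)
  zs <- c(20, 6, 8)
  expected <- sum(w * zs^2.94)^(1 / 2.94)
  expect_equal(effectiveZ(c(Ca = 1, C = 1, O = 3)), unname(expected))
  expect_error(effectiveZ(c(Xx = 1)), "unknown element")
})
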