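test_that("ROI summaries report the standard descriptive statistics", {
  const <- summarizeROI(array(5, c(2, 2, 2)), array(TRUE, c(2, 2, 2)))
  expect_equal(const@mean, 5)
  expect_equal(const@sd, 0)
  expect_equal(const@median, 5)
  expect_equal(c(const@min, const@max), c(5, 5))

  s <- summarizeROI(array(c(1, 2, 3, 4), c(4, 1, 1)), rep(TRUE, 4))
  expect_equal(s@mean, 2.5)
  expect_equal(s@sd, sd(1:4))          # sample (n-1) SD, about 1.291
  expect_equal(s@median, 2.5)          # midpoint of the central pair
  expect_equal(c(s@min, s@max), c(1, 4))
  expect_match(formatROISummary(s),
               "^-?\\d+ ± \\d+ HU; -?\\d+, -?\\d+–-?\\d+ HU$")
  expect_error(summarizeROI(array(1, c(2, 2, 2)), array(FALSE, c(2, 2, 2))),
               "empty ROI")
})

test_that("artifact screening excludes ROIs above the fraction threshold", {
  labels <- array(0L, c(10, 4, 4))
  labels[1:5, 1, 1] <- 1L    # 5 voxels
  labels[, 2, 1] <- 2L       # 10 voxels
  labels[, 3, 1] <- 3L       # 10 voxels
  roles <- data.frame(code = 1:3, structure = "bone", specimen = "x",
                      age_ma = 0, habitat = "terrestrial")
  rois <- roiSet(labels, roles, c(1, 1, 1))

  mask <- array(FALSE, dim(labels))
  screened <- excludeArtifactROIs(rois, mask)
  expect_false(any(roiRoles(screened)$excluded))  # empty mask: keep all

  mask[, 2, 1] <- TRUE                 # ROI 2 fully inside the band
  mask[1, 3, 1] <- TRUE                # ROI 3 at exactly 1/10 contamination
  screened <- excludeArtifactROIs(rois, mask, maxFraction = 0.10)
  ex <- roiRoles(screened)
  expect_identical(ex$excluded, c(FALSE, TRUE, FALSE))  # strict inequality
  expect_match(ex$reason[2], "artifact fraction")
  # brute-force fraction check
  expect_equal(sum(mask[labels == 3L]) / sum(labels == 3L), 0.10)
})

test_that("one-way ANOVA handles degenerate and separated groups", {
  x <- c(1, 1, 1, 1, 1, 1)
  g <- rep(c("a", "b"), each = 3)
  r <- anovaPosthoc(x, g)
  expect_equal(r@F, 0)
  expect_equal(r@p, 1)
  expect_equal(r@pairwise$p_bonferroni, 1)

  set.seed(5)
  y <- c(rnorm(10, 0, 1), rnorm(10, 100, 1))  # 100 SDs apart
  r2 <- anovaPosthoc(y, rep(c("a", "b"), each = 10))
  expect_lt(r2@p, 1e-6)
  expect_true(all(r2@pairwise$significant))
  expect_error(anovaPosthoc(c(1, 2), c("a", "b")), "at least two")
  expect_error(anovaPosthoc(1:3, c("a", "a", "a")), "two groups")
})

test_that("two-group ANOVA reproduces the pooled two-sample t test", {
  set.seed(9)
  for (i in 1:5) {
    x <- rnorm(12); y <- rnorm(9, 0.5)
    r <- anovaPosthoc(c(x, y), rep(c("a", "b"), c(12, 9)))
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(r@F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(r@p, tt$p.value, tolerance = 1e-10)
    expect_equal(r@pairwise$p_raw, tt$p.value, tolerance = 1e-10)
  }
})

test_that("post-hoc adjustments obey Bonferroni and Tukey orderings", {
  set.seed(13)
  for (i in 1:20) {
    k <- sample(3:5, 1)
    n <- sample(5:9, 1)
    x <- rnorm(k * n) + rep(runif(k, 0, 1), each = n)
    r <- anovaPosthoc(x, rep(letters[1:k], each = n))
    pw <- r@pairwise
    m <- nrow(pw)
    expect_equal(pw$p_bonferroni, pmin(1, m * pw$p_raw))
    expect_true(all(pw$p_bonferroni >= pw$p_raw))
    # Tukey HSD is uniformly less conservative than Bonferroni in
    # balanced designs
    expect_true(all(pw$p_tukey <= pw$p_bonferroni + 1e-12))
    expect_true(all(pw$p_raw >= 0 & pw$p_bonferroni <= 1 &
                    pw$p_tukey >= 0 & pw$p_tukey <= 1))
  }
})

test_that("structure contrasts detect real differences and skip singletons", {
  set.seed(17)
  flatVals <- rnorm(10, 500, 120)
  roi <- data.frame(
    specimen = rep(c("fossil", "flat", "lonely"), c(20, 20, 10)),
    structure = c(rep(c("bone", "sediment"), each = 10),
                  rep(c("bone", "sediment"), each = 10),
                  rep("bone", 10)),
    mean = c(rnorm(10, 1800, 120), rnorm(10, 30, 120),  # separated
             flatVals, flatVals,          # identical compositions
             rnorm(10, 100, 120)))
  expect_warning(cs <- contrastStructures(roi), "lonely")
  expect_lt(cs$fossil@p, 0.001)
  expect_equal(cs$flat@F, 0)
  expect_equal(cs$flat@p, 1)
  expect_null(cs$lonely)
})

test_that("age trend detects monotone and violating orderings", {
  roi <- data.frame(
    specimen = rep(c("s0", "s1", "s2"), each = 4),
    age_ma = rep(c(0, 50, 150), each = 4),
    habitat = "terrestrial",
    mean = rep(c(5, 800, 3200), each = 4) + rep(c(-1, 1, -2, 2), 3))
  tr <- ageTrend(roi)
  expect_true(tr$monotone)
  expect_identical(tr$specimens$specimen, c("s0", "s1", "s2"))
  expect_equal(nrow(tr$violations), 0)
  expect_s4_class(tr$posthoc, "GroupComparison")

  shuffled <- roi
  shuffled$mean[shuffled$specimen == "s1"] <- 4000  # older s2 now lower
  tr2 <- ageTrend(shuffled)
  expect_false(tr2$monotone)
  expect_identical(tr2$violations$younger, "s1")
  expect_identical(tr2$violations$older, "s2")

  one <- roi[roi$specimen == "s0", ]
  expect_error(ageTrend(one), "two terrestrial")
})

test_that("the synthetic fossil cohort reproduces the published pattern", {
  coh <- simulateCohort(seed = 1)
  fl <- coh[coh$element == "fluorine", ]

  # bone-vs-sediment fluorine: significant for every sediment-embedded
  # specimen except the marine low-fluorine ichthyosaur configuration
  cs <- suppressWarnings(contrastStructures(fl))
  expect_lt(cs$dysalotosaurus@p, 0.05)
  expect_lt(cs$alcelaphinae@p, 0.05)
  expect_lt(cs$nothosaurus@p, 0.05)
  expect_gt(cs$ichthyosaur@p, 0.05)
  # diseased dentary tissue accumulates more fluorine than healthy tissue
  expect_lt(cs$trex_dentary@p, 0.05)
  dpair <- cs$trex_dentary@pairwise
  expect_gt(abs(dpair$diff), 1000)

  # terrestrial fluorine rises with geological age: extant about 0 HU,
  # oldest terrestrial about 3500 HU
  tr <- ageTrend(fl[fl$structure == "bone", ])
  expect_true(tr$monotone)
  means <- setNames(tr$specimens$mean, tr$specimens$specimen)
  expect_lt(means[["bos_taurus"]], 20)
  expect_gt(means[["dysalotosaurus"]], 3300)
  expect_lt(means[["dysalotosaurus"]], 3700)
  expect_lt(tr$posthoc@p, 0.001)

  # calcium maps separate bone from sediment in the terrestrial specimens
  ca <- coh[coh$element == "calcium", ]
  csCa <- suppressWarnings(contrastStructures(ca))
  expect_lt(csCa$dysalotosaurus@p, 0.05)
})
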