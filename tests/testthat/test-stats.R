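test_that("LOD formula matches hand computation and its limits", {
  # zero-variance limit: LOD collapses to the blank mean
  expect_equal(computeLod(c(5, 5, 5), c(7, 7, 7)), 5)
  expect_equal(computeLod(c(0, 0, 0, 0), c(1, 1, 1, 1)), 0)
  # hand-computed example with an independently tabulated t quantile:
  # mu_B = 2, sigma_B = 1, sigma_S = 2, t_{0.95,4} = 2.13185
  expect_equal(computeLod(c(1, 2, 3), c(2, 4, 6), beta = 0.05, n = 3, f = 4),
               2 + 2.13185 * 3 / sqrt(3), tolerance = 1e-5)
  expect_error(computeLod(c(1), c(2, 3)), "sd undefined")
  expect_error(computeLod(c(1, 2), c(2, 3), beta = 1.5), "beta")
})

test_that("LOD is monotone in its dispersion inputs and decreasing in n", {
  base <- computeLod(c(1, 2, 3), c(2, 4, 6), n = 3, f = 4)
  # inflate blank spread
  expect_gt(computeLod(c(0, 2, 4), c(2, 4, 6), n = 3, f = 4), base)
  # inflate low-level spread
  expect_gt(computeLod(c(1, 2, 3), c(1, 4, 7), n = 3, f = 4), base)
  # shift blank mean up
  expect_gt(computeLod(c(2, 3, 4), c(2, 4, 6), n = 3, f = 4), base)
  # more replicates shrink the add-on term
  expect_lt(computeLod(c(1, 2, 3), c(2, 4, 6), n = 12, f = 4), base)
})

test_that("LOQ is three times the LOD", {
  expect_equal(computeLoq(0.44), 1.32)
  expect_equal(computeLoq(0), 0)
  expect_equal(computeLoq(10), 30)
  expect_error(computeLoq(-1), "non-negative")
  # composed with computeLod for arbitrary valid inputs
  set.seed(3)
  for (i in 1:10) {
    l <- computeLod(rnorm(4, 10), rnorm(4, 20))
    expect_equal(computeLoq(l), 3 * l)
  }
})

test_that("per-level CV is sd/mean in percent and scale-invariant", {
  expect_equal(levelCv(c(10, 10, 10)), 0)
  # sample sd of (8, 12) is 2.8284, mean 10
  expect_equal(levelCv(c(8, 12)), 28.28427, tolerance = 1e-5)
  set.seed(8)
  x <- runif(6, 1, 100)
  expect_equal(levelCv(1000 * x), levelCv(x))
  expect_error(levelCv(c(-1, 1)), "mean is zero")
  expect_error(levelCv(5), ">= 2")
  # the six reported level CVs average to 9.81% (printed at 2 d.p.)
  cvs <- c(26.19, 4.45, 4.84, 10.03, 4.45, 8.93)
  expect_identical(sprintf("%.2f", mean(cvs)), "9.81")
})

test_that("calibration fit recovers exact linearity and ignores level order", {
  levels <- data.frame(nominal = rep(c(1, 10, 100, 1000), each = 3))
  levels$response <- 2 * levels$nominal
  fit <- fitCalibration(levels, blanks = c(0.01, 0.012, 0.011))
  expect_equal(fit@slope, 1, tolerance = 1e-12)
  expect_equal(fit@rSquared, 1, tolerance = 1e-12)
  expect_equal(fit@averageCv, 0)
  expect_equal(loq(fit), 3 * lod(fit))
  shuffled <- levels[sample(nrow(levels)), ]
  fit2 <- fitCalibration(shuffled, blanks = c(0.01, 0.012, 0.011))
  expect_equal(fit2@slope, fit@slope)
  expect_equal(lod(fit2), lod(fit))
  expect_error(fitCalibration(data.frame(nominal = c(1, 1, 2, 2),
                                         response = c(1, 1, 2, 2))),
               ">= 3 distinct")
  neg <- data.frame(nominal = rep(c(1, 10, 100), each = 2),
                    response = c(-1, -2, 20, 20, 200, 200))
  expect_error(fitCalibration(neg), "non-positive")
})

test_that("calibration slope is recovered from noisy simulated series", {
  slopes <- vapply(1:20, function(s) {
    sim <- simulateCalibration(cvModel = 0.10, seed = s)
    fitCalibration(sim$levels, blanks = sim$blanks)@slope
  }, numeric(1))
  expect_lt(abs(median(slopes) - 1), 0.05)
})

test_that("stoichiometry normalization is a guarded quotient", {
  expect_equal(normalizeRatio(2, 4), 0.5)
  expect_equal(normalizeRatio(3, 3), 1)
  expect_equal(normalizeRatio(2 * 7, 4 * 7), normalizeRatio(2, 4))
  expect_error(normalizeRatio(2, 0), "below detection")
})

test_that("group comparison computes fold of means and a Welch p-value", {
  tab <- data.frame(
    sample_id = sprintf("s%d", 1:8),
    group = rep(c("PD", "control"), each = 4),
    py39_amount_fmol = c(2, 4, 6, 8, 1, 2, 3, 4),
    y39_amount_fmol = rep(1, 8))
  tab$normalized_ratio <- tab$py39_amount_fmol / tab$y39_amount_fmol
  gc <- compareGroups(tab, "normalized_ratio")
  # PD values are exactly 2x the control values elementwise
  expect_equal(foldChange(gc), 2)
  expect_match(gc@testName, "Welch")
  # identical groups: fold 1, p = 1
  same <- tab
  same$normalized_ratio <- rep(c(1, 2, 3, 4), 2)
  gc0 <- compareGroups(same, "normalized_ratio")
  expect_equal(foldChange(gc0), 1)
  expect_equal(pValue(gc0), 1)
  # fold change is equivariant in a global case-group scaling
  sc <- tab
  sc$normalized_ratio[sc$group == "PD"] <-
    sc$normalized_ratio[sc$group == "PD"] * 3
  expect_equal(foldChange(compareGroups(sc, "normalized_ratio")),
               3 * foldChange(gc))
  # too-small groups are rejected
  expect_error(compareGroups(tab[c(1, 5, 6, 7, 8), ], "normalized_ratio"),
               ">= 2 samples")
  # the Mann-Whitney alternative is recorded
  expect_match(compareGroups(tab, "normalized_ratio",
                             test = "wilcoxon")@testName, "Mann-Whitney")
})

test_that("sample tables read from CSV and TSV with the ratio added", {
  tab <- data.frame(sample_id = c("a", "b", "c", "d"),
                    group = c("PD", "PD", "control", "control"),
                    py39_amount_fmol = c(1, 2, 1, 1),
                    y39_amount_fmol = c(2, 2, 4, 4))
  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, csv, row.names = FALSE)
  got <- readSampleTable(csv)
  expect_equal(got$normalized_ratio, c(0.5, 1, 0.25, 0.25))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, tsv, sep = "\t", row.names = FALSE)
  expect_equal(readSampleTable(tsv)$normalized_ratio, got$normalized_ratio)
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab[, 1:3], bad, row.names = FALSE)
  expect_error(readSampleTable(bad), "lacks column")
})
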