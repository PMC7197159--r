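test_that("XIC extraction matches centroids within ppm and sums them", {
  ts <- buildTransitionSet(y39_light(), 2L)
  y4 <- fragments(ts)$mz[fragments(ts)$index == 4]
  expect_equal(y4, 390.23471, tolerance = 1e-5)  # independent-table value
  scan1 <- spectrumRecord(msLevel = 2L, retentionTime = 0.5,
                          isolationCenter = 476.261, mz = y4,
                          intensity = 1000)
  traces <- extractXic(list(scan1), ts, ppmTolerance = 10)
  idx <- vapply(traces, function(tr) tr@fragment$index, integer(1))
  expect_equal(vapply(traces, function(tr) tr@intensity, numeric(1)),
               ifelse(idx == 4, 1000, 0))
  # centroid 25 ppm away is invisible at 10 ppm tolerance
  off <- spectrumRecord(msLevel = 2L, retentionTime = 0.5,
                        isolationCenter = 476.261,
                        mz = y4 * (1 + 25e-6), intensity = 1000)
  tr <- extractXic(list(off), ts, ppmTolerance = 10)
  expect_equal(tr[[which(idx == 4)]]@intensity, 0)
  # two centroids inside tolerance are summed
  two <- spectrumRecord(msLevel = 2L, retentionTime = 0.5,
                        isolationCenter = 476.261,
                        mz = y4 * (1 + c(-4e-6, 4e-6)),
                        intensity = c(600, 400))
  tr2 <- extractXic(list(two), ts, ppmTolerance = 10)
  expect_equal(tr2[[which(idx == 4)]]@intensity, 1000)
  expect_error(extractXic(list(scan1), ts, ppmTolerance = 0), "> 0")
})

gauss_traces <- function(apex = 1, fwhm = 0.1, height = 1000,
                         span = c(0, 2), dt = 0.01) {
  rt <- seq(span[1], span[2], by = dt)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  y <- height * exp(-(rt - apex)^2 / (2 * sigma^2))
  list(new("XicTrace",
           fragment = data.frame(series = "y", index = 4L, charge = 1L,
                                 mz = 390.23471),
           rt = rt, intensity = y, ppmTolerance = 10))
}

test_that("peak detection encloses a noiseless Gaussian almost entirely", {
  tr <- gauss_traces()
  pk <- detectPeak(tr)
  expect_true(pk$detected)
  expect_equal(pk$apexRt, 1, tolerance = 1e-9)
  got <- integrateTrace(tr[[1]], c(pk$rtStart, pk$rtEnd))
  # analytic Gaussian area: height * fwhm * 1.064467
  full <- 1000 * 0.1 * 1.064467
  expect_gt(got / full, 0.99)
})

test_that("ties between equal peaks break toward the anchor RT", {
  rt <- seq(0, 2, by = 0.01)
  sigma <- 0.02
  y <- 100 * exp(-(rt - 0.5)^2 / (2 * sigma^2)) +
       100 * exp(-(rt - 1.5)^2 / (2 * sigma^2))
  tr <- list(new("XicTrace",
                 fragment = data.frame(series = "y", index = 4L,
                                       charge = 1L, mz = 390.23471),
                 rt = rt, intensity = y, ppmTolerance = 10))
  expect_equal(detectPeak(tr, anchorRt = 0.5)$apexRt, 0.5, tolerance = 0.02)
  expect_equal(detectPeak(tr, anchorRt = 1.5)$apexRt, 1.5, tolerance = 0.02)
})

test_that("flat or sparse traces give below-detection, not an error", {
  rt <- seq(0, 2, by = 0.02)
  zero <- list(new("XicTrace",
                   fragment = data.frame(series = "y", index = 4L,
                                         charge = 1L, mz = 390.23471),
                   rt = rt, intensity = rep(0, length(rt)),
                   ppmTolerance = 10))
  expect_false(detectPeak(zero)$detected)
  # a single spike is fewer than the minimum 4 non-zero points
  spike <- zero
  spike[[1]]@intensity[50] <- 1e6
  expect_false(detectPeak(spike)$detected)
})

test_that("trapezoidal integration matches closed forms and a fine-grid oracle", {
  rect <- new("XicTrace",
              fragment = data.frame(series = "y", index = 4L, charge = 1L,
                                    mz = 390.23471),
              rt = seq(0, 1, by = 0.1), intensity = rep(100, 11),
              ppmTolerance = 10)
  expect_equal(integrateTrace(rect, c(0, 1)), 100)
  tri <- new("XicTrace",
             fragment = rect@fragment,
             rt = c(0, 0.5, 1), intensity = c(0, 100, 0), ppmTolerance = 10)
  expect_equal(integrateTrace(tri, c(0, 1)), 50)
  expect_error(integrateTrace(rect, c(1, 0)), "inverted")
  expect_error(integrateTrace(rect, c(-1, 0.5)), "span")
  # random traces vs brute-force fine-grid Riemann oracle
  set.seed(99)
  for (i in 1:100) {
    tr <- random_trace(50)
    lo <- tr@rt[5]; hi <- tr@rt[45]
    expect_equal(integrateTrace(tr, c(lo, hi)), riemann_oracle(tr, lo, hi),
                 tolerance = 1e-9)
  }
})

test_that("pair quantification is plain isotope-dilution arithmetic", {
  ts <- buildTransitionSet(py39_light(), 2L)
  mk <- function(total, detected = TRUE) {
    areas <- setNames(rep(total / 6, 6), paste0("y", 3:8))
    if (!detected) areas[] <- 0
    new("PeakQuant", species = ts, rtStart = 0.9, rtEnd = 1.1, apexRt = 1,
        areaPerFragment = areas, totalArea = sum(areas), nPoints = 11L,
        detected = detected)
  }
  r <- quantifyPair(mk(500), mk(1000), spikeFmol = 20)
  expect_equal(ratio(r), 0.5)
  expect_equal(amount(r), 10)
  expect_equal(ratio(quantifyPair(mk(777), mk(777))), 1)
  # light below detection: ratio 0 with the flag
  bd <- quantifyPair(mk(0, detected = FALSE), mk(1000))
  expect_true(bd@belowDetection)
  expect_equal(ratio(bd), 0)
  # missing heavy standard is an assay failure
  expect_error(quantifyPair(mk(500), mk(0, detected = FALSE)),
               "heavy internal standard")
})

test_that("ratios are invariant to global intensity scaling", {
  lset <- buildTransitionSet(py39_light(), 2L)
  hset <- buildTransitionSet(py39_heavy(), 2L)
  run <- simulatePrmRun(list(lset, hset), lightHeavyRatio = 0.3,
                        noise = noiseModel(multiplicativeCv = 0.05,
                                           baselineLevel = 20),
                        seed = 5)
  r1 <- ratio(quantifyRun(run, lset, hset))
  scaled <- prmRun(lapply(scans(run), function(s) {
    s@intensity <- s@intensity * 37.5
    s
  }))
  r2 <- ratio(quantifyRun(scaled, lset, hset))
  expect_equal(r2, r1, tolerance = 1e-12)
})
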