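## Synthetic PRM runs, calibration series and cohort tables with known
## ground truth, so the whole pipeline is testable without instrument data.

#' Elution and noise models for the PRM-run simulator
#'
#' `elutionModel()` describes the chromatographic peak: a Gaussian profile
#' with the given apex, full width at half maximum and height, sampled at a
#' fixed scan interval; `fragmentPattern` gives the relative intensity of
#' each monitored fragment (non-negative, summing to 1). The defaults — a
#' 0.1 min FWHM peak at 1.0 min, scanned every 0.02 min over a 2 min
#' window — emulate a sharp nano-LC peak under a short PRM schedule.
#'
#' `noiseModel()` describes the corruption applied: lognormal
#' multiplicative noise of a given CV on every point, a constant additive
#' baseline, Poisson-placed spurious interference centroids, and Gaussian
#' mass error (ppm) on centroid positions. All defaults are 0, i.e. a
#' noiseless run.
#'
#' @param apexRt apex retention time, minutes.
#' @param fwhm full width at half maximum, minutes (> 0).
#' @param scanInterval time between scans per precursor, minutes (> 0).
#' @param peakHeight summed apex intensity of the heavy species.
#' @param fragmentPattern relative fragment intensities (recycled/normalized
#'   to the fragment count at simulation time); `NULL` uses a monotone rise
#'   to the mid-series, mimicking a y-ion ladder.
#' @param rtSpan `c(start, end)` of the simulated window, minutes.
#' @return a list with class `"elutionModel"`.
#' @export
elutionModel <- function(apexRt = 1.0, fwhm = 0.1, scanInterval = 0.02,
                         peakHeight = 1e6, fragmentPattern = NULL,
                         rtSpan = c(0, 2)) {
  stopifnot(fwhm > 0, scanInterval > 0, rtSpan[1] < rtSpan[2])
  if (!is.null(fragmentPattern)) {
    stopifnot(all(fragmentPattern >= 0))
    if (abs(sum(fragmentPattern) - 1) > 1e-9)
      stop("'fragmentPattern' must sum to 1", call. = FALSE)
  }
  structure(list(apexRt = apexRt, fwhm = fwhm, scanInterval = scanInterval,
                 peakHeight = peakHeight, fragmentPattern = fragmentPattern,
                 rtSpan = rtSpan), class = "elutionModel")
}

#' @param multiplicativeCv lognormal point-noise CV (fraction, e.g. 0.1).
#' @param baselineLevel constant additive baseline intensity.
#' @param interferenceRate expected spurious centroids per scan (Poisson).
#' @param massErrorPpmSd Gaussian centroid mass-error SD, ppm.
#' @rdname elutionModel
#' @export
noiseModel <- function(multiplicativeCv = 0, baselineLevel = 0,
                       interferenceRate = 0, massErrorPpmSd = 0) {
  stopifnot(multiplicativeCv >= 0, baselineLevel >= 0,
            interferenceRate >= 0, massErrorPpmSd >= 0)
  structure(list(multiplicativeCv = multiplicativeCv,
                 baselineLevel = baselineLevel,
                 interferenceRate = interferenceRate,
                 massErrorPpmSd = massErrorPpmSd), class = "noiseModel")
}

## default fragment pattern: monotone rise to the mid-series
.default_pattern <- function(k) {
  w <- pmin(seq_len(k), ceiling(k * 0.6))
  w / sum(w)
}

#' Simulate a targeted PRM run
#'
#' Generates MS2 scans on a regular retention-time grid for each transition
#' set. Per scan, each fragment contributes one centroid at its theoretical
#' m/z perturbed by Gaussian ppm error, with intensity
#' `Gaussian elution x pattern weight x (heavy: 1, light: ratio) x
#' lognormal noise + baseline`; interference centroids are Poisson-placed
#' uniformly over the scan m/z range. The run is fully reproducible from
#' `seed`.
#'
#' @param transitionSets list of [TransitionSet-class]; light species are
#'   scaled by `lightHeavyRatio`, heavy species by 1.
#' @param lightHeavyRatio true light/heavy abundance ratio (>= 0).
#' @param elution an [elutionModel()].
#' @param noise a [noiseModel()].
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return a [PrmRun-class].
#' @export
simulatePrmRun <- function(transitionSets, lightHeavyRatio = 1,
                           elution = elutionModel(), noise = noiseModel(),
                           seed = 1L) {
  stopifnot(lightHeavyRatio >= 0, inherits(elution, "elutionModel"),
            inherits(noise, "noiseModel"))
  withr::with_seed(seed, {
    grid <- seq(elution$rtSpan[1], elution$rtSpan[2],
                by = elution$scanInterval)
    sigma <- elution$fwhm / (2 * sqrt(2 * log(2)))
    lnsd <- if (noise$multiplicativeCv > 0)
      sqrt(log(1 + noise$multiplicativeCv^2)) else 0
    scans <- list()
    for (t in grid) {
      profile <- elution$peakHeight *
        exp(-(t - elution$apexRt)^2 / (2 * sigma^2))
      for (ts in transitionSets) {
        fr <- ts@fragments
        k <- nrow(fr)
        pat <- elution$fragmentPattern
        pat <- if (is.null(pat)) .default_pattern(k) else pat / sum(pat)
        stopifnot(length(pat) == k)
        scale <- if (ts@peptide@label == "light") lightHeavyRatio else 1
        base <- profile * pat * scale
        lnoise <- if (lnsd > 0)
          exp(stats::rnorm(k, -lnsd^2 / 2, lnsd)) else rep(1, k)
        intens <- base * lnoise + noise$baselineLevel
        mzerr <- if (noise$massErrorPpmSd > 0)
          stats::rnorm(k, 0, noise$massErrorPpmSd) else rep(0, k)
        mzv <- fr$mz * (1 + mzerr * 1e-6)
        nint <- stats::rpois(1, noise$interferenceRate)
        if (nint > 0) {
          mzv <- c(mzv, stats::runif(nint, 100, 1100))
          intens <- c(intens, stats::rexp(nint,
            1 / max(noise$baselineLevel, 0.05 * elution$peakHeight)))
        }
        keep <- intens > 0
        mzv <- mzv[keep]; intens <- intens[keep]
        o <- order(mzv)
        mzv <- mzv[o]; intens <- intens[o]
        ## merge pathological coincident centroids
        if (length(mzv) > 1L && any(diff(mzv) <= 0)) {
          agg <- tapply(intens, mzv, sum)
          mzv <- as.numeric(names(agg)); intens <- as.numeric(agg)
        }
        scans[[length(scans) + 1L]] <- spectrumRecord(
          scanId = sprintf("scan=%d", length(scans) + 1L),
          msLevel = 2L, retentionTime = t,
          isolationCenter = ts@precursorMz, isolationWidth = 1.6,
          mz = mzv, intensity = intens)
      }
    }
    prmRun(scans)
  })
}

#' Simulate a calibration series
#'
#' Replicate responses at each nominal amount are
#' `responseSlope x nominal x lognormal(cv)`; blanks are drawn from a
#' Gaussian baseline distribution truncated at 0. Defaults emulate a
#' six-level dilution series from 1 amol to 100 fmol with a few percent to
#' tens of percent replicate CV, the design of a sub-attomole PRM
#' calibration curve.
#'
#' @param nominalAmounts vector of >= 3 nominal amounts (amol).
#' @param replicatesPerLevel replicates per level (>= 2).
#' @param responseSlope response per amol (area units).
#' @param cvModel per-level CV as a single fraction or a vector matching
#'   `nominalAmounts`.
#' @param blankMean,blankSd baseline distribution of the blank responses.
#' @param nBlanks number of blank replicates.
#' @param seed integer seed.
#' @return list with `levels` (data.frame `nominal`, `replicate`,
#'   `response`) and `blanks` (numeric).
#' @export
simulateCalibration <- function(nominalAmounts = c(1, 10, 100, 1e3, 1e4, 1e5),
                                replicatesPerLevel = 3L,
                                responseSlope = 100,
                                cvModel = 0.10,
                                blankMean = 30, blankSd = 10,
                                nBlanks = 4L, seed = 1L) {
  stopifnot(length(nominalAmounts) >= 3L, replicatesPerLevel >= 2L)
  cvs <- rep_len(cvModel, length(nominalAmounts))
  withr::with_seed(seed, {
    levels <- do.call(rbind, lapply(seq_along(nominalAmounts), function(i) {
      mu <- responseSlope * nominalAmounts[i]
      lnsd <- if (cvs[i] > 0) sqrt(log(1 + cvs[i]^2)) else 0
      resp <- if (lnsd > 0)
        mu * exp(stats::rnorm(replicatesPerLevel, -lnsd^2 / 2, lnsd))
      else rep(mu, replicatesPerLevel)
      data.frame(nominal = nominalAmounts[i],
                 replicate = seq_len(replicatesPerLevel), response = resp)
    }))
    blanks <- pmax(stats::rnorm(nBlanks, blankMean, blankSd), 0)
    list(levels = levels, blanks = blanks)
  })
}

#' Simulate a case/control cohort table
#'
#' Generates per-sample phosphopeptide and unmodified-peptide amounts such
#' that the normalized pY/Y ratios are lognormal around group means
#' differing by `foldChange` (case/control). Defaults emulate the assay's
#' cohort design: 4 cases and 4 controls, a control stoichiometry of a few
#' percent, and 15% between-sample CV on the ratio.
#'
#' @param nPerGroup samples per group (>= 2 for downstream comparison).
#' @param controlRatioMean mean normalized ratio in the control group.
#' @param foldChange true case/control ratio of group means.
#' @param betweenSampleCv lognormal between-sample CV of the ratio
#'   (fraction).
#' @param y39MeanFmol,y39Cv distribution of the unmodified-peptide amount.
#' @param caseGroup,controlGroup group labels.
#' @param seed integer seed.
#' @return data.frame with columns `sample_id`, `group`,
#'   `py39_amount_fmol`, `y39_amount_fmol`, `normalized_ratio`.
#' @export
simulateCohort <- function(nPerGroup = 4L, controlRatioMean = 0.04,
                           foldChange = 2.5, betweenSampleCv = 0.15,
                           y39MeanFmol = 5, y39Cv = 0.3,
                           caseGroup = "PD", controlGroup = "control",
                           seed = 1L) {
  stopifnot(foldChange > 0, nPerGroup >= 1L)
  withr::with_seed(seed, {
    lnsd <- if (betweenSampleCv > 0) sqrt(log(1 + betweenSampleCv^2)) else 0
    ylnsd <- if (y39Cv > 0) sqrt(log(1 + y39Cv^2)) else 0
    one_group <- function(label, mu, n, offset) {
      r <- if (lnsd > 0) mu * exp(stats::rnorm(n, -lnsd^2 / 2, lnsd))
           else rep(mu, n)
      y <- if (ylnsd > 0)
        y39MeanFmol * exp(stats::rnorm(n, -ylnsd^2 / 2, ylnsd))
      else rep(y39MeanFmol, n)
      data.frame(sample_id = sprintf("%s_%02d", label, seq_len(n)),
                 group = label, py39_amount_fmol = r * y,
                 y39_amount_fmol = y)
    }
    tab <- rbind(
      one_group(caseGroup, controlRatioMean * foldChange, nPerGroup, 0),
      one_group(controlGroup, controlRatioMean, nPerGroup, nPerGroup))
    tab$normalized_ratio <- tab$py39_amount_fmol / tab$y39_amount_fmol
    tab
  })
}
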