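#' Extract per-fragment ion chromatograms
#'
#' For each fragment of a [TransitionSet-class], builds an [XicTrace-class]
#' over the supplied scans: per scan, the trace intensity is the sum of all
#' centroid intensities within `+/- ppmTolerance` of the fragment m/z; scans
#' with no matching centroid contribute intensity 0 at their retention time.
#' The default 10 ppm matches MS2 acquisition at 30,000 resolution.
#'
#' @param scans list of [SpectrumRecord-class], in retention-time order
#'   (e.g. from [selectTargetedScans()]).
#' @param transitionSet a [TransitionSet-class].
#' @param ppmTolerance extraction half-tolerance in ppm; must be > 0.
#' @return list of [XicTrace-class], one per fragment row.
#' @export
extractXic <- function(scans, transitionSet, ppmTolerance = 10) {
  if (ppmTolerance <= 0) stop("'ppmTolerance' must be > 0", call. = FALSE)
  fr <- transitionSet@fragments
  rt <- vapply(scans, function(s) s@retentionTime, numeric(1))
  lapply(seq_len(nrow(fr)), function(i) {
    target <- fr$mz[i]
    tol <- target * ppmTolerance * 1e-6
    intens <- vapply(scans, function(s) {
      hit <- abs(s@mz - target) <= tol
      if (any(hit)) sum(s@intensity[hit]) else 0
    }, numeric(1))
    new("XicTrace", fragment = fr[i, , drop = FALSE], rt = rt,
        intensity = intens, ppmTolerance = ppmTolerance)
  })
}

## Fragment-summed intensity over traces sharing one RT grid.
.summed_trace <- function(traces) {
  rt <- traces[[1]]@rt
  for (tr in traces)
    if (length(tr@rt) != length(rt) || (length(rt) && any(tr@rt != rt)))
      stop("traces must share a single RT grid", call. = FALSE)
  list(rt = rt, intensity = Reduce(`+`, lapply(traces, slot, "intensity")))
}

#' Detect the quantification peak on a set of chromatograms
#'
#' Works on the fragment-summed trace. Candidate peaks are maximal runs of
#' points above baseline; the chosen candidate maximizes summed intensity,
#' with ties broken by apex proximity to `anchorRt`. Boundaries are then
#' extended outward to the flanking local minima (or the trace ends). A peak
#' must contain at least `minPoints` non-zero points, otherwise the outcome
#' is below-detection (not an error). Detection may optionally run on a
#' 5-point moving average (`smooth = TRUE`); integration never does.
#'
#' @param traces list of [XicTrace-class] on a common RT grid.
#' @param anchorRt optional expected apex RT (minutes), used only to break
#'   ties between equal-intensity candidates.
#' @param baseline baseline level subtracted conceptually before run
#'   finding; default 0.
#' @param minPoints minimum non-zero points across the peak (default 4).
#' @param smooth apply a 5-point moving average for detection only.
#' @return list with elements `detected` (logical), `rtStart`, `rtEnd`,
#'   `apexRt` (minutes; `NA` when not detected) and `indices` (integer
#'   positions of the peak on the RT grid).
#' @export
detectPeak <- function(traces, anchorRt = NULL, baseline = 0,
                       minPoints = 4L, smooth = FALSE) {
  st <- .summed_trace(traces)
  rt <- st$rt
  y_raw <- st$intensity
  y <- y_raw
  if (smooth && length(y_raw) >= 5L) {
    f <- as.numeric(stats::filter(y_raw, rep(1 / 5, 5), sides = 2))
    y <- ifelse(is.na(f), y_raw, f)
  }
  none <- list(detected = FALSE, rtStart = NA_real_, rtEnd = NA_real_,
               apexRt = NA_real_, indices = integer())
  if (length(y) == 0L || max(y) <= baseline) return(none)
  ## maximal runs above baseline (plus a 1% dynamic-range floor so a flat
  ## noise pedestal does not merge everything into one run)
  thr <- baseline + 0.01 * (max(y) - baseline)
  above <- y > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- Map(seq, starts[r$values], ends[r$values])
  if (!length(runs)) return(none)
  sums <- vapply(runs, function(ix) sum(y[ix]), numeric(1))
  ## relative tolerance so symmetric twin peaks count as tied
  best <- which(sums >= max(sums) * (1 - 1e-9))
  if (length(best) > 1L && !is.null(anchorRt)) {
    apexes <- vapply(runs[best],
                     function(ix) rt[ix[which.max(y[ix])]], numeric(1))
    best <- best[which.min(abs(apexes - anchorRt))]
  } else best <- best[1L]
  ix <- runs[[best]]
  ## extend to flanking local minima or trace ends
  lo <- ix[1L]
  while (lo > 1L && y[lo - 1L] < y[lo]) lo <- lo - 1L
  hi <- ix[length(ix)]
  while (hi < length(y) && y[hi + 1L] < y[hi]) hi <- hi + 1L
  ix <- lo:hi
  if (sum(y_raw[ix] > 0) < minPoints) return(none)
  apex <- ix[which.max(y[ix])]
  list(detected = TRUE, rtStart = rt[lo], rtEnd = rt[hi], apexRt = rt[apex],
       indices = ix)
}

#' Trapezoidal peak integration
#'
#' Integrates intensity over retention time within the boundaries by the
#' trapezoid rule (units intensity x minutes). Boundaries that fall between
#' grid points are handled by linear interpolation at the boundary
#' positions. No baseline is subtracted.
#'
#' @param trace an [XicTrace-class].
#' @param boundaries `c(rtStart, rtEnd)` in minutes, within the trace span.
#' @return area in intensity x min.
#' @export
integrateTrace <- function(trace, boundaries) {
  if (boundaries[1] > boundaries[2])
    stop("inverted boundaries", call. = FALSE)
  rt <- trace@rt
  y <- trace@intensity
  if (boundaries[1] < rt[1] || boundaries[2] > rt[length(rt)])
    stop("boundaries outside the trace RT span", call. = FALSE)
  inside <- rt > boundaries[1] & rt < boundaries[2]
  xs <- c(boundaries[1], rt[inside], boundaries[2])
  ys <- c(stats::approx(rt, y, boundaries[1])$y, y[inside],
          stats::approx(rt, y, boundaries[2])$y)
  sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
}

#' Integrate all fragments of one species over fixed boundaries
#'
#' @param traces list of [XicTrace-class] for the species (common RT grid).
#' @param species the [TransitionSet-class] the traces belong to.
#' @param peak a detection result from [detectPeak()], or a below-detection
#'   outcome.
#' @return a [PeakQuant-class]; `detected = FALSE` with zero areas when the
#'   peak was not detected.
#' @export
integratePeak <- function(traces, species, peak) {
  frnames <- vapply(traces, function(tr)
    sprintf("%s%d", tr@fragment$series, tr@fragment$index), character(1))
  if (!isTRUE(peak$detected)) {
    areas <- stats::setNames(rep(0, length(traces)), frnames)
    return(new("PeakQuant", species = species, rtStart = NA_real_,
               rtEnd = NA_real_, apexRt = NA_real_, areaPerFragment = areas,
               totalArea = 0, nPoints = 0L, detected = FALSE))
  }
  b <- c(peak$rtStart, peak$rtEnd)
  areas <- stats::setNames(
    vapply(traces, integrateTrace, numeric(1), boundaries = b), frnames)
  new("PeakQuant", species = species, rtStart = peak$rtStart,
      rtEnd = peak$rtEnd, apexRt = peak$apexRt, areaPerFragment = areas,
      totalArea = sum(areas), nPoints = length(peak$indices),
      detected = TRUE)
}

#' Light/heavy ratio and spike-anchored absolute amount
#'
#' Standard stable-isotope-dilution readout: `ratio = light area / heavy
#' area` and `amount = ratio x spike`. The heavy internal standard must be
#' detected (its area anchors the quantification); a light species that
#' failed detection yields ratio 0 with `belowDetection = TRUE`. Both areas
#' are expected to be integrated over the heavy peak's boundaries (see
#' [quantifyRun()]).
#'
#' @param light [PeakQuant-class] of the endogenous (light) species.
#' @param heavy [PeakQuant-class] of the heavy internal standard.
#' @param spikeFmol amount of heavy standard spiked (fmol); assay default
#'   20 fmol.
#' @param coelutionR optional Pearson correlation of the light and heavy
#'   summed traces across the peak (see [quantifyRun()]).
#' @return a [RatioResult-class].
#' @export
quantifyPair <- function(light, heavy, spikeFmol = 20,
                         coelutionR = NA_real_) {
  if (!heavy@detected || heavy@totalArea <= 0)
    stop("assay failure: heavy internal standard not detected",
         call. = FALSE)
  below <- !light@detected
  r <- if (below) 0 else light@totalArea / heavy@totalArea
  new("RatioResult", lightArea = light@totalArea,
      heavyArea = heavy@totalArea, ratio = r, amount = r * spikeFmol,
      coelutionR = coelutionR, belowDetection = below)
}

#' Quantify one light/heavy species pair in one run
#'
#' The full per-run workflow: select targeted scans per precursor, extract
#' fragment chromatograms, detect the peak on the heavy standard (always
#' abundant), integrate both species over the heavy peak's boundaries, and
#' form the light/heavy ratio. Co-elution is reported as the Pearson
#' correlation of the fragment-summed light trace (interpolated onto the
#' heavy RT grid where the schedules differ) with the heavy trace across
#' the peak.
#'
#' @param run a [PrmRun-class].
#' @param lightSet,heavySet [TransitionSet-class] of the light and heavy
#'   species.
#' @param ppmTolerance fragment extraction tolerance (ppm).
#' @param rtWindow scheduling window `c(min, max)` in minutes.
#' @param spikeFmol heavy spike amount (fmol).
#' @param anchorRt optional expected apex RT for tie-breaking.
#' @return a [RatioResult-class].
#' @export
quantifyRun <- function(run, lightSet, heavySet, ppmTolerance = 10,
                        rtWindow = c(0, Inf), spikeFmol = 20,
                        anchorRt = NULL) {
  hs <- selectTargetedScans(run, heavySet@precursorMz, rtWindow)
  ls <- selectTargetedScans(run, lightSet@precursorMz, rtWindow)
  htr <- extractXic(hs, heavySet, ppmTolerance)
  ltr <- extractXic(ls, lightSet, ppmTolerance)
  hpeak <- detectPeak(htr, anchorRt = anchorRt)
  if (!hpeak$detected)
    stop("assay failure: heavy internal standard not detected",
         call. = FALSE)
  hq <- integratePeak(htr, heavySet, hpeak)
  ## light integrated over the heavy boundaries; detection on the light
  ## traces restricted to those boundaries decides below_detection
  lsum <- .summed_trace(ltr)
  lwin <- lsum$rt >= hpeak$rtStart & lsum$rt <= hpeak$rtEnd
  ldetected <- sum(lsum$intensity[lwin] > 0) >= 4L
  lq <- if (ldetected) {
    integratePeak(ltr, lightSet, hpeak)
  } else {
    integratePeak(ltr, lightSet, list(detected = FALSE))
  }
  ## co-elution: light summed trace interpolated onto the heavy peak grid
  hsum <- .summed_trace(htr)
  hix <- hpeak$indices
  co <- NA_real_
  if (length(hix) >= 3L && length(lsum$rt) >= 2L) {
    li <- stats::approx(lsum$rt, lsum$intensity, xout = hsum$rt[hix],
                        rule = 2)$y
    if (stats::sd(li) > 0 && stats::sd(hsum$intensity[hix]) > 0)
      co <- stats::cor(li, hsum$intensity[hix])
  }
  quantifyPair(lq, hq, spikeFmol = spikeFmol, coelutionR = co)
}

#' @export
setMethod("show", "XicTrace", function(object) {
  cat(sprintf("XicTrace %s%d (%.4f Th, +/-%g ppm): %d point(s)\n",
              object@fragment$series, object@fragment$index,
              object@fragment$mz, object@ppmTolerance, length(object@rt)))
})

#' @export
setMethod("show", "PeakQuant", function(object) {
  if (object@detected)
    cat(sprintf(
      "PeakQuant: RT %.3f-%.3f min (apex %.3f), total area %.4g over %d fragment(s)\n",
      object@rtStart, object@rtEnd, object@apexRt, object@totalArea,
      length(object@areaPerFragment)))
  else cat("PeakQuant: below detection\n")
})

#' @export
setMethod("show", "RatioResult", function(object) {
  cat(sprintf(
    "RatioResult: light/heavy = %.6g, amount = %.6g fmol%s (coelution r = %s)\n",
    object@ratio, object@amount,
    if (object@belowDetection) " [below detection]" else "",
    ifelse(is.na(object@coelutionR), "NA",
           sprintf("%.4f", object@coelutionR))))
})
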