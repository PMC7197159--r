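#' Construct a single scan record
#'
#' @param scanId scan identifier; autogenerated when `NA`.
#' @param msLevel 1 or 2.
#' @param retentionTime minutes.
#' @param isolationCenter precursor isolation window center (Th); `NA` for
#'   MS1 scans.
#' @param isolationWidth full isolation window width (Th); the assay default
#'   is 1.6 Th.
#' @param mz strictly increasing centroid m/z array.
#' @param intensity matching non-negative intensities.
#' @return a [SpectrumRecord-class].
#' @export
spectrumRecord <- function(scanId = NA_character_, msLevel = 2L,
                           retentionTime = 0, isolationCenter = NA_real_,
                           isolationWidth = 1.6, mz = numeric(),
                           intensity = numeric()) {
  new("SpectrumRecord", scanId = as.character(scanId),
      msLevel = as.integer(msLevel), retentionTime = retentionTime,
      isolationCenter = isolationCenter, isolationWidth = isolationWidth,
      mz = as.numeric(mz), intensity = as.numeric(intensity))
}

#' Assemble scans into a run
#'
#' Scans are sorted by retention time (duplicate RTs keep input order, which
#' keeps interleaved multi-precursor PRM schedules stable).
#'
#' @param scans list of [SpectrumRecord-class].
#' @param sourcePath provenance path, "" for in-memory runs.
#' @return a [PrmRun-class].
#' @export
prmRun <- function(scans = list(), sourcePath = "") {
  if (length(scans)) {
    rt <- vapply(scans, function(s) s@retentionTime, numeric(1))
    scans <- scans[order(rt)]  # stable sort: ties keep input order
    span <- max(rt) - min(rt)
  } else span <- 0
  new("PrmRun", scans = scans, sourcePath = sourcePath, runSpan = span)
}

#' Read a PRM run from mzML
#'
#' Reads an mzML 1.1 file (centroided spectra expected) into a
#' [PrmRun-class]. Retention times are converted to minutes regardless of
#' the source unit (mzML stores seconds). An absent isolation width falls
#' back to `defaultIsolationWidth`, matching the acquisition setting of the
#' Y39 assay (1.6 Th).
#'
#' @param path mzML file path.
#' @param defaultIsolationWidth isolation width (Th) assumed when the file
#'   carries none.
#' @return a [PrmRun-class] with scans in retention-time order.
#' @seealso [writeRun()], [selectTargetedScans()]
#' @export
readRun <- function(path, defaultIsolationWidth = 1.6) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  fh <- mzR::openMSfile(path, backend = "pwiz")
  on.exit(mzR::close(fh), add = TRUE)
  hd <- mzR::header(fh)
  n <- nrow(hd)
  if (n == 0L) return(prmRun(list(), sourcePath = path))
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)
  if (!is.null(hd$centroided) &&
      any(!is.na(hd$centroided) & !hd$centroided & hd$msLevel == 2L))
    warning("profile-mode MS2 spectra found; treating points as centroids",
            call. = FALSE)
  scans <- vector("list", n)
  for (i in seq_len(n)) {
    m <- pk[[i]]
    ctr <- hd$isolationWindowTargetMZ[i]
    if (is.null(ctr) || is.na(ctr)) ctr <- hd$precursorMZ[i]
    lo <- hd$isolationWindowLowerOffset[i]
    hi <- hd$isolationWindowUpperOffset[i]
    width <- if (!is.null(lo) && !is.na(lo) && !is.na(hi) && (lo + hi) > 0)
      lo + hi else defaultIsolationWidth
    lvl <- hd$msLevel[i]
    scans[[i]] <- spectrumRecord(
      scanId = if (!is.null(hd$spectrumId)) hd$spectrumId[i] else
        as.character(hd$acquisitionNum[i]),
      msLevel = lvl,
      retentionTime = hd$retentionTime[i] / 60,  # mzML RT is seconds
      isolationCenter = if (lvl >= 2L) ctr else NA_real_,
      isolationWidth = width,
      mz = m[, 1], intensity = m[, 2])
  }
  prmRun(scans, sourcePath = path)
}

#' Write scans to mzML
#'
#' Writes a [PrmRun-class] (or list of [SpectrumRecord-class]) as mzML with
#' 64-bit m/z and 32-bit intensity encoding, so that
#' `readRun(writeRun(x))` returns bit-equal m/z arrays. Scans are sorted by
#' retention time before writing; all records are validated before any
#' output is produced.
#'
#' @param run a [PrmRun-class] or list of [SpectrumRecord-class].
#' @param path output mzML path.
#' @return `path`, invisibly.
#' @export
writeRun <- function(run, path) {
  scans <- if (is(run, "PrmRun")) run@scans else {
    for (s in run) stopifnot(is(s, "SpectrumRecord"))
    run
  }
  for (s in scans) validObject(s)  # reject before any write
  if (length(scans)) {
    rt <- vapply(scans, function(s) s@retentionTime, numeric(1))
    scans <- scans[order(rt)]
  }
  n <- length(scans)
  if (n == 0L) {
    ## valid empty run: header with zero rows
    hdr <- .mzml_header(list())
    mzR::writeMSData(list(), file = path, header = hdr, outformat = "mzml")
    return(invisible(path))
  }
  hdr <- .mzml_header(scans)
  pks <- lapply(scans, function(s) cbind(mz = s@mz, intensity = s@intensity))
  mzR::writeMSData(pks, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}

.mzml_header <- function(scans) {
  n <- length(scans)
  g <- function(f, default) if (n) vapply(scans, f, numeric(1)) else numeric()
  rt_sec <- g(function(s) s@retentionTime * 60)
  lvl <- if (n) vapply(scans, function(s) s@msLevel, integer(1)) else integer()
  ctr <- g(function(s) if (is.na(s@isolationCenter)) 0 else s@isolationCenter)
  halfw <- g(function(s) s@isolationWidth / 2)
  npk <- if (n) vapply(scans, function(s) length(s@mz), integer(1)) else
    integer()
  tic <- g(function(s) sum(s@intensity))
  bpi <- g(function(s) if (length(s@intensity)) max(s@intensity) else 0)
  bpm <- g(function(s) if (length(s@intensity))
    s@mz[which.max(s@intensity)] else 0)
  data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = lvl,
    polarity = rep(1L, n), peaksCount = npk, totIonCurrent = tic,
    retentionTime = rt_sec, basePeakMZ = bpm, basePeakIntensity = bpi,
    collisionEnergy = rep(25, n), ionisationEnergy = rep(0, n),
    lowMZ = g(function(s) if (length(s@mz)) min(s@mz) else 0),
    highMZ = g(function(s) if (length(s@mz)) max(s@mz) else 0),
    precursorScanNum = rep(0L, n), precursorMZ = ctr,
    precursorCharge = as.integer(ifelse(lvl >= 2L, 2L, 0L)),
    precursorIntensity = rep(0, n), mergedScan = rep(0L, n),
    mergedResultScanNum = rep(0L, n), mergedResultStartScanNum = rep(0L, n),
    mergedResultEndScanNum = rep(0L, n), injectionTime = rep(0, n),
    filterString = rep(NA_character_, n),
    spectrumId = if (n) vapply(scans, function(s) s@scanId, character(1))
      else character(),
    centroided = rep(TRUE, n), ionMobilityDriftTime = rep(NA_real_, n),
    isolationWindowTargetMZ = ctr, isolationWindowLowerOffset = halfw,
    isolationWindowUpperOffset = halfw,
    scanWindowLowerLimit = rep(NA_real_, n),
    scanWindowUpperLimit = rep(NA_real_, n))
}

#' Select the targeted MS2 scans for one precursor
#'
#' Returns, in retention-time order, the MS2 scans whose isolation window
#' contains the precursor (`|isolation center - precursor m/z| <= width/2`)
#' and whose retention time lies within `rtWindow`. With the assay's 1.6 Th
#' windows the two phosphopeptide precursors (516.244 and 520.251 Th) land
#' in disjoint scan sets.
#'
#' @param run a [PrmRun-class].
#' @param precursorMz target precursor m/z (Th).
#' @param rtWindow `c(min, max)` retention-time window in minutes.
#' @return list of [SpectrumRecord-class] (possibly empty).
#' @export
selectTargetedScans <- function(run, precursorMz, rtWindow = c(0, Inf)) {
  if (rtWindow[1] >= rtWindow[2])
    stop("'rtWindow' must satisfy min < max", call. = FALSE)
  keep <- vapply(run@scans, function(s) {
    s@msLevel == 2L && !is.na(s@isolationCenter) &&
      abs(s@isolationCenter - precursorMz) <= s@isolationWidth / 2 &&
      s@retentionTime >= rtWindow[1] && s@retentionTime <= rtWindow[2]
  }, logical(1))
  run@scans[keep]
}

#' @export
setMethod("show", "PrmRun", function(object) {
  cat(sprintf("PrmRun: %d scan(s) spanning %.3f min", length(object@scans),
              object@runSpan))
  if (nzchar(object@sourcePath)) cat(" <", object@sourcePath, ">")
  cat("\n")
})

#' @export
setMethod("show", "SpectrumRecord", function(object) {
  cat(sprintf("SpectrumRecord MS%d @ %.4f min, %d centroid(s)",
              object@msLevel, object@retentionTime, length(object@mz)))
  if (!is.na(object@isolationCenter))
    cat(sprintf(", isolation %.4f +/- %.2f Th", object@isolationCenter,
                object@isolationWidth / 2))
  cat("\n")
})
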