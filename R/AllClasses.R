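#' Class "Modification": a site-localized mass modification
#'
#' A named monoisotopic mass shift together with the residue letter (or
#' terminus keyword) it may occupy. Instances normally come from the built-in
#' registry (see [modificationRegistry()]) rather than being constructed
#' directly.
#'
#' @slot name single character, e.g. `"phospho"`.
#' @slot deltaMass monoisotopic mass shift in Da; must be finite.
#' @slot siteSpec character vector of residue letters the modification may
#'   sit on, or `"N-term"` / `"C-term"`.
#'
#' @seealso [modificationRegistry()], [registerModification()]
#' @exportClass Modification
setClass("Modification",
  representation(name = "character", deltaMass = "numeric",
                 siteSpec = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
      msg <- c(msg, "'name' must be a single non-empty string")
    if (length(object@deltaMass) != 1L || !is.finite(object@deltaMass))
      msg <- c(msg, "'deltaMass' must be a single finite number")
    if (length(object@siteSpec) < 1L)
      msg <- c(msg, "'siteSpec' must name at least one residue or terminus")
    if (length(msg)) msg else TRUE
  }
)

#' Class "ModifiedPeptide": a peptide with modifications and a label state
#'
#' A peptide sequence over the 20 standard residues, a set of site-localized
#' modifications (1-based positions within the peptide), and a stable-isotope
#' label state. The heavy state models a \eqn{^{13}C_6,^{15}N_2}-lysine
#' label on the C-terminal K (+8.0142 Da).
#'
#' @slot sequence uppercase amino-acid string.
#' @slot mods data.frame with columns `position` (integer, 1-based),
#'   `name` (character) and `deltaMass` (numeric); zero rows when unmodified.
#' @slot label `"light"` or `"heavy"`.
#'
#' @seealso [modifiedPeptide()], [peptideNeutralMass()], [precursorMz()]
#' @exportClass ModifiedPeptide
setClass("ModifiedPeptide",
  representation(sequence = "character", mods = "data.frame",
                 label = "character"),
  validity = function(object) {
    msg <- character()
    seq <- object@sequence
    if (length(seq) != 1L || !nzchar(seq))
      msg <- c(msg, "'sequence' must be a single non-empty string")
    else {
      bad <- setdiff(strsplit(seq, "")[[1]], names(.AA_MONO))
      if (length(bad))
        msg <- c(msg, sprintf("unknown residue letter(s): %s",
                              paste(unique(bad), collapse = ", ")))
    }
    if (!all(c("position", "name", "deltaMass") %in% names(object@mods)))
      msg <- c(msg, "'mods' must have columns position, name, deltaMass")
    else if (nrow(object@mods)) {
      pos <- object@mods$position
      if (any(pos < 1L | pos > nchar(seq)))
        msg <- c(msg, "modification position outside 1..length(sequence)")
      if (anyDuplicated(object@mods[, c("position", "name")]))
        msg <- c(msg, "at most one modification per position per name")
    }
    if (!(length(object@label) == 1L && object@label %in% c("light", "heavy")))
      msg <- c(msg, "'label' must be \"light\" or \"heavy\"")
    if (length(msg)) msg else TRUE
  }
)

#' Class "TransitionSet": the monitored species for one peptide
#'
#' Precursor m/z and charge for one [ModifiedPeptide-class] species together
#' with the fragment ions monitored for it.
#'
#' @slot peptide the [ModifiedPeptide-class].
#' @slot precursorMz precursor m/z (Th); consistent with the peptide neutral
#'   mass and charge to within 1e-4 Th.
#' @slot precursorCharge positive integer.
#' @slot fragments data.frame with columns `series` ("b"/"y"), `index`,
#'   `charge`, `mz`; at least one row.
#'
#' @seealso [buildTransitionSet()], [exportTransitionList()]
#' @exportClass TransitionSet
setClass("TransitionSet",
  representation(peptide = "ModifiedPeptide", precursorMz = "numeric",
                 precursorCharge = "integer", fragments = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (object@precursorCharge < 1L)
      msg <- c(msg, "'precursorCharge' must be >= 1")
    expect <- (peptideNeutralMass(object@peptide) +
               object@precursorCharge * .MASS_PROTON) / object@precursorCharge
    if (abs(expect - object@precursorMz) > 1e-4)
      msg <- c(msg, sprintf(
        "precursorMz %.5f inconsistent with peptide mass (expected %.5f)",
        object@precursorMz, expect))
    fr <- object@fragments
    if (!all(c("series", "index", "charge", "mz") %in% names(fr)))
      msg <- c(msg, "'fragments' must have columns series, index, charge, mz")
    else {
      if (nrow(fr) == 0L) msg <- c(msg, "'fragments' must be non-empty")
      if (nrow(fr) && any(fr$mz <= 0)) msg <- c(msg, "fragment mz must be > 0")
      if (nrow(fr) && any(fr$index >= nchar(object@peptide@sequence)))
        msg <- c(msg, "fragment index must be < peptide length")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Class "SpectrumRecord": one targeted scan
#'
#' A single (usually MS2/PRM) scan: centroid m/z and intensity arrays plus
#' the retention time and, for MS2, the precursor isolation window.
#'
#' @slot scanId scan identifier.
#' @slot msLevel 1 or 2.
#' @slot retentionTime minutes, non-negative.
#' @slot isolationCenter isolation window center (Th); `NA` for MS1.
#' @slot isolationWidth full isolation window width (Th).
#' @slot mz strictly increasing centroid m/z array.
#' @slot intensity non-negative intensities, same length as `mz`.
#'
#' @seealso [spectrumRecord()], [readRun()], [selectTargetedScans()]
#' @exportClass SpectrumRecord
setClass("SpectrumRecord",
  representation(scanId = "character", msLevel = "integer",
                 retentionTime = "numeric", isolationCenter = "numeric",
                 isolationWidth = "numeric", mz = "numeric",
                 intensity = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@mz) != length(object@intensity))
      msg <- c(msg, "'mz' and 'intensity' must have equal length")
    if (length(object@mz) > 1L && any(diff(object@mz) <= 0))
      msg <- c(msg, "'mz' must be strictly increasing")
    if (length(object@intensity) && any(object@intensity < 0))
      msg <- c(msg, "intensities must be non-negative")
    if (!(object@msLevel %in% c(1L, 2L)))
      msg <- c(msg, "'msLevel' must be 1 or 2")
    if (!is.na(object@retentionTime) && object@retentionTime < 0)
      msg <- c(msg, "'retentionTime' must be non-negative")
    if (length(msg)) msg else TRUE
  }
)

#' Class "PrmRun": an ordered collection of scans from one run
#'
#' @slot scans list of [SpectrumRecord-class], ordered by retention time.
#' @slot sourcePath path the run was read from ("" for in-memory runs).
#' @slot runSpan total run span in minutes.
#'
#' @seealso [readRun()], [writeRun()]
#' @exportClass PrmRun
setClass("PrmRun",
  representation(scans = "list", sourcePath = "character",
                 runSpan = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@scans)) {
      if (!all(vapply(object@scans, is, logical(1), "SpectrumRecord")))
        msg <- c(msg, "'scans' must all be SpectrumRecord objects")
      else {
        rt <- vapply(object@scans, function(s) s@retentionTime, numeric(1))
        if (is.unsorted(rt)) msg <- c(msg, "scans must be ordered by RT")
      }
    }
    if (length(msg)) msg else TRUE
  }
)

#' Class "XicTrace": an extracted ion chromatogram for one fragment
#'
#' @slot fragment one-row data.frame describing the fragment
#'   (series, index, charge, mz).
#' @slot rt strictly increasing retention times (minutes).
#' @slot intensity non-negative intensities, same length as `rt`.
#' @slot ppmTolerance extraction tolerance (ppm).
#'
#' @seealso [extractXic()]
#' @exportClass XicTrace
setClass("XicTrace",
  representation(fragment = "data.frame", rt = "numeric",
                 intensity = "numeric", ppmTolerance = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@rt) != length(object@intensity))
      msg <- c(msg, "'rt' and 'intensity' must have equal length")
    if (length(object@rt) > 1L && any(diff(object@rt) <= 0))
      msg <- c(msg, "'rt' must be strictly increasing")
    if (length(object@intensity) && any(object@intensity < 0))
      msg <- c(msg, "intensities must be non-negative")
    if (length(msg)) msg else TRUE
  }
)

#' Class "PeakQuant": integrated peak areas for one species in one run
#'
#' @slot species the [TransitionSet-class] quantified.
#' @slot rtStart,rtEnd peak boundaries (minutes).
#' @slot apexRt apex retention time (minutes), within the boundaries.
#' @slot areaPerFragment named numeric, area per fragment (intensity x min).
#' @slot totalArea sum of per-fragment areas.
#' @slot nPoints number of chromatogram points across the peak.
#' @slot detected FALSE when the species failed peak detection.
#'
#' @seealso [integratePeak()], [quantifyPair()]
#' @exportClass PeakQuant
setClass("PeakQuant",
  representation(species = "TransitionSet", rtStart = "numeric",
                 rtEnd = "numeric", apexRt = "numeric",
                 areaPerFragment = "numeric", totalArea = "numeric",
                 nPoints = "integer", detected = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@detected) {
      if (!(object@rtStart < object@apexRt || object@rtStart == object@apexRt) ||
          object@apexRt > object@rtEnd)
        msg <- c(msg, "apex must lie within the peak boundaries")
    }
    if (object@totalArea < 0) msg <- c(msg, "'totalArea' must be >= 0")
    if (abs(object@totalArea - sum(object@areaPerFragment)) >
        1e-9 * max(1, object@totalArea))
      msg <- c(msg, "'totalArea' must equal the sum of per-fragment areas")
    if (length(msg)) msg else TRUE
  }
)

#' Class "RatioResult": light/heavy quantification for one species pair
#'
#' @slot lightArea,heavyArea integrated areas over the shared boundaries.
#' @slot ratio light/heavy area ratio (dimensionless, >= 0).
#' @slot amount absolute amount, `ratio x spike` (fmol).
#' @slot coelutionR Pearson correlation of the light and heavy
#'   fragment-summed traces across the peak; NA when undefined.
#' @slot belowDetection TRUE when the light peak failed detection.
#'
#' @seealso [quantifyPair()], [quantifyRun()]
#' @exportClass RatioResult
setClass("RatioResult",
  representation(lightArea = "numeric", heavyArea = "numeric",
                 ratio = "numeric", amount = "numeric",
                 coelutionR = "numeric", belowDetection = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@ratio < 0) msg <- c(msg, "'ratio' must be >= 0")
    if (!is.na(object@coelutionR) &&
        (object@coelutionR < -1 || object@coelutionR > 1))
      msg <- c(msg, "'coelutionR' must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
  }
)

#' Class "CalibrationResult": fitted response curve with LOD/LOQ
#'
#' Log-log calibration fit (log10 mean response vs log10 nominal amount)
#' with per-level coefficients of variation, blank-based limit of detection
#' and the 3 x LOD limit of quantification.
#'
#' @slot slope,intercept coefficients of the log-log least-squares line.
#' @slot rSquared coefficient of determination of that fit.
#' @slot lod limit of detection, amount units (attomoles in the default assay).
#' @slot loq limit of quantification, always `3 * lod`.
#' @slot levels data.frame: `nominal`, `meanResponse`, `cvPercent`, `n`.
#' @slot averageCv unweighted mean of the per-level CVs (percent).
#'
#' @seealso [fitCalibration()], [computeLod()], [computeLoq()]
#' @exportClass CalibrationResult
setClass("CalibrationResult",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", lod = "numeric", loq = "numeric",
                 levels = "data.frame", averageCv = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.na(object@lod) && abs(object@loq - 3 * object@lod) >
        1e-9 * max(1, object@lod))
      msg <- c(msg, "'loq' must equal 3 * lod")
    if (!is.na(object@rSquared) &&
        (object@rSquared < 0 || object@rSquared > 1 + 1e-12))
      msg <- c(msg, "'rSquared' must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  }
)

#' Class "GroupComparison": two-group comparison of a per-sample quantity
#'
#' @slot groupMeans named numeric, mean per group.
#' @slot foldChange ratio of group means (case group / control group).
#' @slot pValue p-value of the location test.
#' @slot testName the test used (recorded so alternatives are auditable).
#' @slot value which per-sample quantity was compared.
#'
#' @seealso [compareGroups()]
#' @exportClass GroupComparison
setClass("GroupComparison",
  representation(groupMeans = "numeric", foldChange = "numeric",
                 pValue = "numeric", testName = "character",
                 value = "character"),
  validity = function(object) {
    if (all(object@groupMeans > 0) && object@foldChange <= 0)
      "foldChange must be > 0 when both group means are > 0"
    else TRUE
  }
)
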