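#' @rdname peptideNeutralMass
#' @export
setGeneric("peptideNeutralMass",
           function(p) standardGeneric("peptideNeutralMass"))

#' @rdname precursorMz
#' @export
setGeneric("precursorMz",
           function(p, charge = 2L) standardGeneric("precursorMz"))

#' @rdname fragmentSeries
#' @export
setGeneric("fragmentSeries",
           function(p, series = c("y", "b"), charge = 1L)
             standardGeneric("fragmentSeries"))

#' Accessors for quantification results
#'
#' Small accessor generics for the core result classes, so downstream code
#' never touches slots directly: `ratio()` and `amount()` read a
#' [RatioResult-class]; `lod()`, `loq()` and `averageCv()` read a
#' [CalibrationResult-class]; `foldChange()` and `pValue()` read a
#' [GroupComparison-class]; `fragments()` reads a [TransitionSet-class];
#' `scans()` reads a [PrmRun-class].
#'
#' @param object the object to read from.
#' @return the corresponding scalar, data.frame or list.
#' @name accessors
#' @aliases ratio amount lod loq averageCv foldChange pValue fragments scans
#' @examples
#' p <- modifiedPeptide("EGVLYVGSK", mods = list(phospho = 5))
#' ts <- buildTransitionSet(p, precursorCharge = 2L)
#' nrow(fragments(ts))
NULL

#' @rdname accessors
#' @export
setGeneric("ratio", function(object) standardGeneric("ratio"))
#' @rdname accessors
#' @export
setGeneric("amount", function(object) standardGeneric("amount"))
#' @rdname accessors
#' @export
setGeneric("lod", function(object) standardGeneric("lod"))
#' @rdname accessors
#' @export
setGeneric("loq", function(object) standardGeneric("loq"))
#' @rdname accessors
#' @export
setGeneric("averageCv", function(object) standardGeneric("averageCv"))
#' @rdname accessors
#' @export
setGeneric("foldChange", function(object) standardGeneric("foldChange"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("fragments", function(object) standardGeneric("fragments"))
#' @rdname accessors
#' @export
setGeneric("scans", function(object) standardGeneric("scans"))

#' @rdname accessors
#' @export
setMethod("ratio", "RatioResult", function(object) object@ratio)
#' @rdname accessors
#' @export
setMethod("amount", "RatioResult", function(object) object@amount)
#' @rdname accessors
#' @export
setMethod("lod", "CalibrationResult", function(object) object@lod)
#' @rdname accessors
#' @export
setMethod("loq", "CalibrationResult", function(object) object@loq)
#' @rdname accessors
#' @export
setMethod("averageCv", "CalibrationResult", function(object) object@averageCv)
#' @rdname accessors
#' @export
setMethod("foldChange", "GroupComparison", function(object) object@foldChange)
#' @rdname accessors
#' @export
setMethod("pValue", "GroupComparison", function(object) object@pValue)
#' @rdname accessors
#' @export
setMethod("fragments", "TransitionSet", function(object) object@fragments)
#' @rdname accessors
#' @export
setMethod("scans", "PrmRun", function(object) object@scans)
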