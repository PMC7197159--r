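#' Blank-based limit of detection
#'
#' Computes \deqn{LOD = \mu_B + t_{1-\beta,f}\,(\sigma_B + \sigma_S)/\sqrt{n}}
#' where \eqn{\mu_B} and \eqn{\sigma_B} are the mean and sample standard
#' deviation of blank measurements, \eqn{\sigma_S} the sample standard
#' deviation of the lowest-concentration measurements, \eqn{t_{1-\beta,f}}
#' the one-sided t quantile at probability \eqn{1-\beta} on \eqn{f} degrees
#' of freedom, and \eqn{n} the replicate count. The default
#' \eqn{\beta = 0.05} uses the 95th percentile of the t distribution; the
#' default \eqn{f} is the pooled-variance convention
#' `length(blanks) + length(lowLevel) - 2`. The result is in the units of
#' the inputs (areas convert to amounts via the calibration curve in
#' [fitCalibration()]).
#'
#' @param blanks >= 2 blank measurements.
#' @param lowLevel >= 2 measurements at the lowest concentration level.
#' @param beta type-II error rate in (0, 1); default 0.05.
#' @param n replicate count used in the formula; defaults to
#'   `length(lowLevel)`.
#' @param f degrees of freedom for the t quantile; defaults to
#'   `length(blanks) + length(lowLevel) - 2`.
#' @return the LOD, in the input units.
#' @examples
#' computeLod(c(1, 2, 3), c(2, 4, 6), beta = 0.05, n = 3, f = 4)  # 5.6925
#' @export
computeLod <- function(blanks, lowLevel, beta = 0.05,
                       n = length(lowLevel),
                       f = length(blanks) + length(lowLevel) - 2L) {
  if (length(blanks) < 2L || length(lowLevel) < 2L)
    stop("need >= 2 blank and >= 2 low-level measurements (sd undefined)",
         call. = FALSE)
  if (beta <= 0 || beta >= 1) stop("'beta' must be in (0, 1)", call. = FALSE)
  if (n < 1L) stop("'n' must be >= 1", call. = FALSE)
  mean(blanks) +
    stats::qt(1 - beta, df = f) * (stats::sd(blanks) + stats::sd(lowLevel)) /
      sqrt(n)
}

#' Limit of quantification
#'
#' The LOQ is estimated as three times the LOD, so an LOD of 0.44 amol
#' yields an LOQ of 1.32 amol.
#'
#' @param lod a non-negative LOD.
#' @return `3 * lod`, same units.
#' @examples
#' computeLoq(0.44)  # 1.32
#' @export
computeLoq <- function(lod) {
  if (lod < 0) stop("'lod' must be non-negative", call. = FALSE)
  3 * lod
}

#' Per-level coefficient of variation
#'
#' `100 x sample sd / mean`, the replicate precision reported per
#' calibration level.
#'
#' @param values >= 2 replicate measurements with non-zero mean.
#' @return CV in percent.
#' @examples
#' levelCv(c(8, 12))  # 35.355...
#' @export
levelCv <- function(values) {
  if (length(values) < 2L)
    stop("need >= 2 replicate values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("CV undefined: mean is zero", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Fit a calibration curve with LOD/LOQ and per-level CVs
#'
#' Fits `log10(mean response) ~ log10(nominal amount)` by least squares.
#' The log-log scale is used because the series spans several orders of
#' magnitude (1 amol to 100 fmol in the Y39 assay), where a linear-scale
#' fit would be dominated by the top level. The LOD comes from
#' [computeLod()] on the blanks and the lowest level's replicates; when the
#' responses are areas it is converted to amount units by inverting the
#' fitted power law. The LOQ is `3 x LOD` and the average CV is the
#' unweighted mean of the per-level CVs.
#'
#' @param levels data.frame with columns `nominal` (amount, e.g. amol) and
#'   `response` (one row per replicate); >= 3 distinct nominal amounts.
#' @param blanks >= 2 blank responses (same units as `response`); `NULL`
#'   skips LOD/LOQ estimation.
#' @param responseUnit `"area"` (convert LOD to amount via the curve) or
#'   `"amount"` (responses are already back-calculated amounts).
#' @param beta,n,f passed to [computeLod()]; defaults as there.
#' @return a [CalibrationResult-class].
#' @export
fitCalibration <- function(levels, blanks = NULL,
                           responseUnit = c("area", "amount"),
                           beta = 0.05, n = NULL, f = NULL) {
  responseUnit <- match.arg(responseUnit)
  stopifnot(all(c("nominal", "response") %in% names(levels)))
  nominal <- sort(unique(levels$nominal))
  if (length(nominal) < 3L)
    stop("need >= 3 distinct nominal amounts", call. = FALSE)
  if (any(nominal <= 0))
    stop("nominal amounts must be positive", call. = FALSE)
  per <- do.call(rbind, lapply(nominal, function(a) {
    v <- levels$response[levels$nominal == a]
    data.frame(nominal = a, meanResponse = mean(v),
               cvPercent = levelCv(v), n = length(v))
  }))
  if (any(per$meanResponse <= 0))
    stop("non-positive mean response under log transform at nominal: ",
         paste(per$nominal[per$meanResponse <= 0], collapse = ", "),
         call. = FALSE)
  fit <- stats::lm(log10(meanResponse) ~ log10(nominal), data = per)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  tss <- sum((log10(per$meanResponse) - mean(log10(per$meanResponse)))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  r2 <- min(max(r2, 0), 1)
  lodv <- NA_real_
  if (!is.null(blanks)) {
    low <- levels$response[levels$nominal == nominal[1]]
    args <- list(blanks = blanks, lowLevel = low, beta = beta)
    if (!is.null(n)) args$n <- n
    if (!is.null(f)) args$f <- f
    lodv <- do.call(computeLod, args)
    if (responseUnit == "area") {
      ## invert the fitted power law: amount = 10^((log10(area) - b) / m)
      lodv <- if (lodv <= 0) 0 else 10^((log10(lodv) - intercept) / slope)
    }
  }
  new("CalibrationResult", slope = slope, intercept = intercept,
      rSquared = r2, lod = lodv,
      loq = if (is.na(lodv)) NA_real_ else computeLoq(lodv),
      levels = per, averageCv = mean(per$cvPercent))
}

#' Phosphopeptide stoichiometry: normalized pY/Y ratio
#'
#' Normalizes the phosphopeptide amount in a sample by the amount of its
#' unmodified counterpart measured in the same sample, giving a
#' stoichiometry-style readout that is robust to changes in total protein
#' level (total synuclein is itself decreased in Parkinson's disease CSF,
#' which is why the raw phosphopeptide amount alone is not used).
#'
#' @param pyAmount phosphopeptide amount (fmol).
#' @param yAmount unmodified-counterpart amount (fmol); must be > 0.
#' @return `pyAmount / yAmount` (dimensionless).
#' @export
normalizeRatio <- function(pyAmount, yAmount) {
  if (any(yAmount <= 0))
    stop("normalizer below detection: unmodified-peptide amount must be > 0",
         call. = FALSE)
  pyAmount / yAmount
}

#' Read a per-sample quantification table
#'
#' Reads the tab- or comma-separated per-sample table consumed by
#' [compareGroups()]: columns `sample_id`, `group` (`PD` / `control`),
#' `py39_amount_fmol`, `y39_amount_fmol`. The normalized pY39/Y39 ratio is
#' added as column `normalized_ratio`.
#'
#' @param path file path (delimiter sniffed from the header line).
#' @return data.frame with the four input columns plus `normalized_ratio`.
#' @export
readSampleTable <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "py39_amount_fmol", "y39_amount_fmol")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("sample table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tab$normalized_ratio <- normalizeRatio(tab$py39_amount_fmol,
                                         tab$y39_amount_fmol)
  tab
}

#' Two-group comparison of a per-sample quantity
#'
#' Compares a per-sample quantity (phosphopeptide amount, unmodified-peptide
#' amount, or their normalized ratio) between a case and a control group.
#' The fold change is the ratio of group means (case/control); the p-value
#' comes from a two-sided Welch unequal-variance t-test by default, with a
#' Mann-Whitney (Wilcoxon rank-sum) alternative. The test used is recorded
#' in the result.
#'
#' @param samples data.frame as returned by [readSampleTable()] (or built
#'   by [simulateCohort()]).
#' @param value which column to compare: `"normalized_ratio"`,
#'   `"py39_amount_fmol"` or `"y39_amount_fmol"`.
#' @param caseGroup,controlGroup group labels; defaults `"PD"`/`"control"`.
#' @param test `"welch"` or `"wilcoxon"`.
#' @return a [GroupComparison-class].
#' @export
compareGroups <- function(samples,
                          value = c("normalized_ratio", "py39_amount_fmol",
                                    "y39_amount_fmol"),
                          caseGroup = "PD", controlGroup = "control",
                          test = c("welch", "wilcoxon")) {
  value <- match.arg(value)
  test <- match.arg(test)
  x <- samples[[value]][samples$group == caseGroup]
  y <- samples[[value]][samples$group == controlGroup]
  if (length(x) < 2L || length(y) < 2L)
    stop("need >= 2 samples per group", call. = FALSE)
  p <- if (test == "welch")
    stats::t.test(x, y, var.equal = FALSE)$p.value
  else
    stats::wilcox.test(x, y, exact = FALSE)$p.value
  means <- stats::setNames(c(mean(x), mean(y)), c(caseGroup, controlGroup))
  new("GroupComparison", groupMeans = means,
      foldChange = mean(x) / mean(y), pValue = p,
      testName = if (test == "welch") "Welch two-sided t-test"
                 else "Mann-Whitney U test",
      value = value)
}

#' @export
setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf(
    "CalibrationResult: log-log slope %.4f, R^2 %.5f, %d level(s)\n",
    object@slope, object@rSquared, nrow(object@levels)))
  cat(sprintf("  LOD %.4g, LOQ %.4g (amount units); average CV %.2f%%\n",
              object@lod, object@loq, object@averageCv))
})

#' @export
setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison of %s: fold change %.4g (%s/%s), p = %.3g [%s]\n",
              object@value, object@foldChange,
              names(object@groupMeans)[1], names(object@groupMeans)[2],
              object@pValue, object@testName))
})
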