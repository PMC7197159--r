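# Shared fixtures for the synuclein Y39 assay.

py39_light <- function() modifiedPeptide("EGVLYVGSK", mods = list(phospho = 5))
py39_heavy <- function()
  modifiedPeptide("EGVLYVGSK", mods = list(phospho = 5), label = "heavy")
y39_light <- function() modifiedPeptide("EGVLYVGSK")
y39_heavy <- function() modifiedPeptide("EGVLYVGSK", label = "heavy")

# Independent residue-mass oracle: a second copy of the standard
# monoisotopic table, typed in separately from the package's constants and
# summed by plain arithmetic. Used to cross-check the implementation's
# cumulative-sum fragment machinery.
ORACLE_AA <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00918, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04048,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
ORACLE_WATER <- 18.010565
ORACLE_PROTON <- 1.007276

oracle_neutral <- function(seq, mod_delta = 0) {
  sum(ORACLE_AA[strsplit(seq, "")[[1]]]) + ORACLE_WATER + mod_delta
}

random_peptide <- function(len) {
  paste(sample(names(ORACLE_AA), len, replace = TRUE), collapse = "")
}

# Random chromatogram for integration oracles.
random_trace <- function(npts = 50) {
  rt <- sort(runif(npts, 0, 5))
  rt <- rt + seq_len(npts) * 1e-9  # guard strict monotonicity
  new("XicTrace",
      fragment = data.frame(series = "y", index = 4L, charge = 1L,
                            mz = 390.23471),
      rt = rt, intensity = runif(npts, 0, 1000), ppmTolerance = 10)
}

# Brute-force fine-grid oracle for integrating the piecewise-linear
# chromatogram model: a dense grid refined with the trace's own knots,
# summed cell by cell with plain arithmetic.
riemann_oracle <- function(trace, lo, hi, n = 1e4) {
  xs <- sort(unique(c(seq(lo, hi, length.out = n),
                      trace@rt[trace@rt > lo & trace@rt < hi])))
  ys <- approx(trace@rt, trace@intensity, xout = xs)$y
  total <- 0
  for (i in seq_len(length(xs) - 1L))
    total <- total + (xs[i + 1L] - xs[i]) * (ys[i] + ys[i + 1L]) / 2
  total
}
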