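## Monoisotopic mass constants.
##
## Residue masses are the standard monoisotopic amino-acid residue table
## (peptide-bond residues, i.e. amino acid minus water). These constants
## reproduce the monitored precursor m/z values of the synuclein Y39 assay
## (516.244 / 520.251 / 476.261 / 480.268 at z = 2) to 3 decimal places.

#' @keywords internal
.AA_MONO <- c(
  G =  57.02146372, A =  71.03711379, S =  87.03202841, P =  97.05276385,
  V =  99.06841392, T = 101.04767847, C = 103.00918448, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857751,
  K = 128.09496302, E = 129.04259309, M = 131.04048461, H = 137.05891186,
  F = 147.06841392, R = 156.10111102, Y = 163.06332853, W = 186.07931295
)

#' @keywords internal
.MASS_WATER <- 18.010564684

#' @keywords internal
.MASS_PROTON <- 1.007276466

## Heavy label: 13C6,15N2-lysine, 6 x (13C - 12C) + 2 x (15N - 14N)
#' @keywords internal
.MASS_HEAVY_K <- 8.01420
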