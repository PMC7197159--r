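---
title: "Targeted PRM quantification of phosphopeptide stoichiometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted PRM quantification of phosphopeptide stoichiometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphoPRM)
```

# The assay

Parallel reaction monitoring (PRM) is a targeted MS2 acquisition mode: a
preselected precursor is isolated (here in a 1.6 Th window) in every cycle
and all of its fragment ions are recorded at high resolution. phosphoPRM
implements the computational half of a stable-isotope-dilution PRM assay
for a low-abundance phosphopeptide, built around the tryptic peptide
EGVLYVGSK shared by α- and β-synuclein. The peptide spans protein residue
Tyr-39; its phosphorylated form (pY39, phospho on peptide position 5,
+79.96633 Da) is a candidate cerebrospinal-fluid readout of c-Abl kinase
activity in Parkinson's disease.

Four species are monitored at charge 2: the phosphopeptide and its
unmodified counterpart, each as the endogenous "light" form and as a
synthetic heavy internal standard carrying a ¹³C₆,¹⁵N₂-lysine label
(+8.0142 Da on the C-terminal K). From the standard monoisotopic residue
table, one water (18.010565 Da) and the proton mass (1.007276 Da), the
doubly protonated precursors are 516.244 (pY39 light), 520.251 (pY39
heavy), 476.261 (unmodified light) and 480.268 Th (unmodified heavy):

```{r transitions}
py <- modifiedPeptide("EGVLYVGSK", mods = list(phospho = 5))
round(precursorMz(py, 2L), 3)
fragmentSeries(py, "y", 1L)
```

Quantification is anchored on the heavy spike: a known amount (20 fmol by
default) of heavy standard is added to each sample, and the endogenous
amount is `light/heavy area ratio × spike`. The biomarker readout is the
*stoichiometry* — the pY39 amount normalized by the unmodified Y39 amount
measured in the same sample — because total synuclein itself changes
between groups; the ratio cancels that.

# The quantification model and its assumptions

For each species, per-fragment extracted ion chromatograms (XICs) are
built by summing, scan by scan, all centroid intensities within a ±ppm
window of the theoretical fragment m/z (default 10 ppm, matched to MS2 at
30,000 resolution). Scans with no matching centroid contribute zero at
their retention time, keeping the RT grid complete.

Peak detection runs on the fragment-summed trace of the **heavy**
standard, which is always abundant by design. Candidate peaks are maximal
runs of points above baseline (with a 1% dynamic-range floor so a flat
noise pedestal does not merge the whole trace into one run); the candidate
with the largest summed intensity wins, ties broken by apex proximity to
an optional anchor RT; boundaries extend outward to the flanking local
minima or the trace ends. The light species is then integrated over the
*heavy* peak's boundaries. This heavy-anchored scheme is standard
isotope-dilution practice for co-eluting label pairs: it makes the ratio
immune to where exactly a noisy light trace would have placed its own
boundaries, and baseline drift outside the peak cannot move it.

Integration is the plain trapezoid rule over retention time (intensity ×
min), with no baseline subtraction by default — the exactness of this
choice is what lets the test suite check integration against a closed-form
oracle to 1e-9. An optional constant-baseline subtraction (median of the
lowest intensity decile) and an optional 5-point moving average exist, the
latter for detection only: smoothing before integration biases areas, so
it is never applied there.

Assumptions worth stating: the light and heavy species co-elute (true for
isotope pairs); the +8.014 Da label separation is large enough at 30,000
resolution that no cross-channel interference correction is needed; and a
detected peak must contain at least 4 non-zero points, below which the
species is reported below-detection rather than quantified from a single
spike. Co-elution quality is reported as a Pearson correlation of the
summed light and heavy traces across the peak but is not used as a hard
filter by default.

# Calibration statistics

The limit of detection follows the blank-based formula

$$\mathrm{LOD} = \mu_B + t_{1-\beta,f}\,\frac{\sigma_B + \sigma_S}{\sqrt{n}}$$

with $\mu_B,\sigma_B$ the mean and sample SD of blank measurements,
$\sigma_S$ the sample SD of the lowest-concentration replicates, $n$ the
replicate count, and $t_{1-\beta,f}$ the one-sided t quantile
($\beta = 0.05$ by default, i.e. the 95th percentile). The degrees of
freedom are not pinned down by the formula itself; the package defaults to
the pooled-variance convention $f = n_B + n_S - 2$, and both $\beta$ and
$f$ are configurable. The LOQ is defined as $3\times$LOD throughout. When
the calibration responses are areas, the LOD is converted to amount units
by inverting the fitted response curve.

The calibration curve is fit as log₁₀(mean response) vs log₁₀(nominal
amount). The series spans five orders of magnitude (1 amol to 100 fmol in
the default design), where ordinary linear-scale least squares would be
dominated entirely by the top level; on the log-log scale each level
carries equal weight and a slope of 1 indicates proportional response.
Replicate precision is summarized per level as CV = 100·sd/mean, and the
curve's average CV is the *unweighted* mean of the level CVs.

Group comparison reports the fold change as the ratio of group means of
the chosen per-sample quantity, and a p-value from a two-sided Welch
unequal-variance t-test by default (a Mann–Whitney alternative is
available; the test used is always recorded in the output). Ratio of
means rather than mean of per-sample ratios was chosen to match how
grouped bar-style summaries are computed; with lognormal between-sample
variation the two differ only by a second-order term at the CVs involved.
No multiple-testing correction is applied — the assay has a single
analyte.

# What the synthetic generator emulates — and what it does not

`simulatePrmRun()` places, for each transition set, MS2 scans on a regular
RT grid (default: every 0.02 min over a 2 min window). Each fragment
contributes one centroid at its theoretical m/z perturbed by Gaussian ppm
error, with intensity

> Gaussian elution profile × fragment pattern weight × (heavy: 1, light:
> ratio) × lognormal noise + baseline,

plus Poisson-placed uniform interference centroids. The defaults (apex
1.0 min, FWHM 0.1 min, fragment pattern rising monotonically to the
mid-series) emulate a sharp nano-LC peak of a mid-length tryptic y-ion
ladder. The lognormal noise is mean-corrected
($e^{\mu - \sigma^2/2}$ parameterization) so that multiplicative noise
does not bias areas, and every simulator is a pure function of its seed.

`simulateCalibration()` draws replicate responses as slope × nominal ×
lognormal(CV) over a six-level 1 amol–100 fmol design with Gaussian
blanks, and `simulateCohort()` generates a 4-vs-4 case/control table whose
normalized ratios are lognormal around group means differing by a chosen
fold change (default 2.5, between-sample CV 15%, control stoichiometry
0.04 — a few-percent phosphorylation occupancy, typical of regulatory
phosphotyrosine sites).

The generator deliberately omits chromatographic tailing, isotope
envelopes, detector saturation and RT drift between runs. Passing tests
therefore demonstrate that the extraction–integration–ratio machinery is
*correct* (it recovers known truths under the stated noise model), not
that the assay performs at any particular level on real instrument data;
real-data behaviour enters only through the acquisition parameters the
defaults mirror (1.6 Th isolation, 10 ppm at 30k resolution, 20 fmol
spike).

# Numerical choices and degenerate inputs

- All m/z math is kept at full double precision; rounding to the 3
  decimals conventionally printed happens only at presentation.
- mzML is written with 64-bit m/z and 32-bit intensity encoding, so m/z
  arrays round-trip bit-exactly while files stay small; retention times
  are stored in seconds (the mzML convention) and always returned in
  minutes.
- Peak-candidate ties are compared with a 1e-9 relative tolerance so that
  two symmetric peaks of equal analytic area tie (and resolve by anchor)
  instead of being split by floating-point noise.
- An all-zero or sub-4-point trace is a *below-detection outcome*, not an
  error; a missing heavy standard is an *assay failure* error, because
  nothing downstream is interpretable without the internal standard.
- A blank or low-level set with fewer than 2 values is rejected (sample
  SD undefined); a zero mean makes the CV undefined and is rejected
  likewise.
- Zero-variance calibration inputs collapse the LOD to the blank mean
  exactly, which the tests use as a closed-form limit.

# Problem sizes used in the test suite

The simulation-backed checks run at deliberately small scale so the whole
suite stays fast and deterministic: 101 scans per precursor per run,
20-seed medians for ratio recovery at four true ratios, 50-seed medians
for the 4-vs-4 cohort fold-change recovery, 100 random traces for the
integration oracle and 50 random peptides for fragment-series
complementarity. These sizes were chosen as the smallest at which the
median-based recovery criteria are stable, and they are stated here so
that a reader re-running the suite knows what was actually exercised.

# Known limitations

- Only b/y fragment series are modeled (HCD behaviour); no neutral-loss
  channels are generated, which is appropriate for phospho-tyrosine
  (stable under HCD) but would need extension for labile phospho-Ser/Thr
  assays.
- One peptide, one charge state per transition set; proteome-wide
  digestion, isotope-envelope prediction and retention-time prediction
  are out of scope.
- No RT alignment or interference scoring across runs; each run is
  quantified independently against its own internal standard.
- The mapping from peptide position 5 to protein residue Tyr-39 is
  configuration metadata, not computed from a protein database.
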