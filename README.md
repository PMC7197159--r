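# phosphoPRM

Targeted quantification of site-phosphorylated peptides by parallel
reaction monitoring (PRM) with stable-isotope dilution, for assay
developers and proteomics analysts who need the whole computational chain
— transition math, mzML chromatogram extraction, peak integration,
calibration statistics and group comparison — in one scriptable, testable
R package rather than spread across a GUI workflow.

The built-in assay targets EGVLYVGSK, the tryptic peptide of α- and
β-synuclein spanning protein residue Tyr-39, whose phosphorylated form
(pY39) in cerebrospinal fluid is a candidate readout of c-Abl activation
in Parkinson's disease. The package is equally usable for any peptide /
modification / heavy-label combination via its modification registry and
assay configuration.

## The model

Four species are monitored at charge 2: phospho and unmodified peptide,
each light (endogenous) and heavy (¹³C₆,¹⁵N₂-lysine internal standard,
+8.0142 Da). Precursors compute to 516.244 / 520.251 / 476.261 / 480.268
Th. Per run, per species, fragment XICs (singly charged y₃–y₈ by default,
±10 ppm) are summed; the peak is detected on the heavy standard and both
species are integrated by the trapezoid rule over the heavy peak's
boundaries, giving

    ratio  = light area / heavy area
    amount = ratio × spike (20 fmol default)

The biomarker readout per sample is the stoichiometry pY39/Y39. Detection
limits follow the blank-based formula

    LOD = μ_B + t₍₁₋β,f₎ (σ_B + σ_S)/√n,   LOQ = 3 × LOD

with a log–log calibration fit, per-level CVs (100·sd/mean) and their
unweighted mean. Group comparison reports fold change as the ratio of
group means and a two-sided Welch t-test p-value (Mann–Whitney optional).
A seeded synthetic generator produces PRM runs (Gaussian elution,
lognormal noise, Poisson interference, ppm mass error), calibration
series and case/control cohorts with known ground truth.

## Worked example

```r
library(phosphoPRM)

light <- buildTransitionSet(modifiedPeptide("EGVLYVGSK", mods = list(phospho = 5)))
heavy <- buildTransitionSet(modifiedPeptide("EGVLYVGSK", mods = list(phospho = 5),
                                            label = "heavy"))
light
#> TransitionSet EGVLY[+80.0]VGSK: precursor 516.2441 Th (z=2), 6 fragment(s)

run <- simulatePrmRun(list(light, heavy), lightHeavyRatio = 0.08,
                      noise = noiseModel(multiplicativeCv = 0.05, baselineLevel = 50,
                                         interferenceRate = 0.2, massErrorPpmSd = 2),
                      seed = 11)
quantifyRun(run, light, heavy, spikeFmol = 20)
#> RatioResult: light/heavy = 0.08326, amount = 1.6652 fmol (coelution r = 0.9995)
```

The simulated endogenous level (true ratio 0.08, i.e. 1.6 fmol against
the 20 fmol spike) is recovered as 1.6652 fmol under 5% multiplicative
noise with baseline and interference; the co-elution correlation near 1
confirms the light/heavy pair integrated over one shared peak.

```r
sim <- simulateCalibration(seed = 11)
fitCalibration(sim$levels, blanks = sim$blanks)
#> CalibrationResult: log-log slope 1.0015, R^2 0.99979, 6 level(s)
#>   LOD 0.3883, LOQ 1.165 (amount units); average CV 7.41%

tab <- simulateCohort(nPerGroup = 4, foldChange = 2.5, seed = 11)
compareGroups(tab, "normalized_ratio")
#> GroupComparison of normalized_ratio: fold change 2.396 (PD/control), p = 0.00109 [Welch two-sided t-test]
```

A slope near 1 with R² ≈ 1 indicates proportional response across the
1 amol–100 fmol series; LOQ is by definition three times LOD. The 4-vs-4
cohort simulated at a true 2.5-fold stoichiometry shift is recovered at
2.396 with Welch p ≈ 1e-3.

A command-line wrapper (`inst/scripts/phosphoprm`) exposes the same
workflow as `transitions`, `simulate`, `quantify`, `calibrate` and
`compare` subcommands with `--config`, `--out-dir`, `--seed`, `--ppm` and
`--verbose` flags.

## Documentation

The methods vignette
(`vignettes/targeted-prm-quantification.Rmd`) describes the
quantification model and its assumptions, the calibration statistics, the
noise model behind the synthetic generator, numerical edge cases and
known limitations.
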