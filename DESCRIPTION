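Package: phosphoPRM
Title: Targeted PRM Quantification of Phosphopeptides with Heavy
    Internal Standards
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computational workflow for parallel reaction monitoring (PRM)
    assays of site-phosphorylated peptides quantified by stable-isotope
    dilution, built around the tyrosine-39 phosphopeptide EGVLYVGSK shared
    by alpha- and beta-synuclein. Computes monoisotopic precursor and
    fragment m/z for modified, isotope-labeled peptides and exports
    transition lists; reads and writes mzML PRM runs; extracts per-fragment
    ion chromatograms, detects and integrates co-eluting light/heavy peak
    pairs, and converts light/heavy area ratios to absolute amounts against
    a heavy spike; fits calibration curves with per-level coefficients of
    variation and blank-based limits of detection and quantification; and
    compares phosphopeptide stoichiometry (phospho/unmodified ratio)
    between sample groups. A synthetic PRM-run, calibration-series and
    cohort generator with known ground truth makes the full pipeline
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    mzR,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
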