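test_that("neutral mass follows residue + water + modification additivity", {
  # single residue: G + water, against the independent table
  expect_equal(peptideNeutralMass(modifiedPeptide("G")), 75.03203,
               tolerance = 1e-6)
  # phosphopeptide: brute-force oracle sum + phospho delta
  expect_equal(peptideNeutralMass(py39_light()),
               oracle_neutral("EGVLYVGSK", 79.96633), tolerance = 1e-6)
  # mass additivity: concat of two chains loses one water
  for (i in 1:10) {
    a <- random_peptide(sample(3:8, 1))
    b <- random_peptide(sample(3:8, 1))
    expect_equal(
      peptideNeutralMass(modifiedPeptide(paste0(a, b))),
      peptideNeutralMass(modifiedPeptide(a)) +
        peptideNeutralMass(modifiedPeptide(b)) - 18.010564684,
      tolerance = 1e-9)
  }
})

test_that("heavy label adds exactly 8.01420 Da on C-terminal K", {
  for (p in list(c("EGVLYVGSK", "EGVLYVGSK"), c("AAK", "AAK"))) {
    light <- modifiedPeptide(p[1])
    heavy <- modifiedPeptide(p[2], label = "heavy")
    expect_equal(peptideNeutralMass(heavy) - peptideNeutralMass(light),
                 8.01420)
  }
  expect_error(modifiedPeptide("EGVLYVGSR", label = "heavy"),
               "C-terminal K")
})

test_that("invalid peptides are rejected with the offending detail", {
  expect_error(modifiedPeptide("EGXLK"), "X")
  expect_error(modifiedPeptide("AAK", mods = list(phospho = 9)), "outside")
  expect_error(modifiedPeptide("AAK", mods = list(phospho = 1)),
               "cannot occupy")
  expect_error(modifiedPeptide("AYK", mods = list(nosuchmod = 2)),
               "unknown modification")
})

test_that("the four monitored precursor m/z values reproduce to 3 d.p.", {
  expect_identical(sprintf("%.3f", precursorMz(py39_light(), 2L)), "516.244")
  expect_identical(sprintf("%.3f", precursorMz(py39_heavy(), 2L)), "520.251")
  expect_identical(sprintf("%.3f", precursorMz(y39_light(), 2L)), "476.261")
  expect_identical(sprintf("%.3f", precursorMz(y39_heavy(), 2L)), "480.268")
  # phospho shifts the z=2 precursor by +39.983165 Th
  expect_equal(precursorMz(py39_light(), 2L) - precursorMz(y39_light(), 2L),
               39.983165)
  expect_error(precursorMz(y39_light(), 0L), "positive")
})

test_that("y/b series carry modifications on the correct fragments", {
  ys_mod <- fragmentSeries(py39_light(), "y", 1L)
  ys_un <- fragmentSeries(y39_light(), "y", 1L)
  # y1..y4 unaffected by phospho at position 5; y5..y8 shifted by it
  expect_equal(ys_mod$mz[1:4], ys_un$mz[1:4])
  expect_equal(ys_mod$mz[5:8], ys_un$mz[5:8] + 79.96633)
  bs_mod <- fragmentSeries(py39_light(), "b", 1L)
  bs_un <- fragmentSeries(y39_light(), "b", 1L)
  expect_equal(bs_mod$mz[1:4], bs_un$mz[1:4])
  expect_equal(bs_mod$mz[5:8], bs_un$mz[5:8] + 79.96633)
  # heavy label in every y ion, in no b ion
  expect_equal(fragmentSeries(y39_heavy(), "y", 1L)$mz, ys_un$mz + 8.01420)
  expect_equal(fragmentSeries(y39_heavy(), "b", 1L)$mz, bs_un$mz)
  # y1 values against the independent table
  expect_equal(ys_un$mz[1], 147.11280, tolerance = 1e-6)
  expect_equal(fragmentSeries(y39_heavy(), "y", 1L)$mz[1], 155.12700,
               tolerance = 1e-6)
})

test_that("b/y complementarity holds for random peptides", {
  set.seed(42)
  for (i in 1:50) {
    p <- modifiedPeptide(random_peptide(sample(5:15, 1)))
    nm <- peptideNeutralMass(p)
    ys <- fragmentSeries(p, "y", 1L)$mz
    bs <- fragmentSeries(p, "b", 1L)$mz
    # mz(b_k) + mz(y_{n-k}) - 2 protons = neutral mass, every k
    expect_equal(bs + rev(ys) - 2 * 1.007276466,
                 rep(nm, length(bs)), tolerance = 1e-9)
  }
})

test_that("transition sets apply the default y3..y8 selection", {
  ts <- buildTransitionSet(py39_light(), 2L)
  expect_equal(nrow(fragments(ts)), 6L)
  expect_equal(fragments(ts)$index, 3:8)
  expect_true(all(fragments(ts)$series == "y"))
  expect_identical(sprintf("%.3f", ts@precursorMz), "516.244")
  expect_identical(
    sprintf("%.3f", buildTransitionSet(y39_heavy(), 2L)@precursorMz),
    "480.268")
  # y9 of a 9-mer does not exist
  expect_error(
    buildTransitionSet(py39_light(), 2L,
                       data.frame(series = "y", index = 9L, charge = 1L)),
    "index")
  expect_error(
    buildTransitionSet(py39_light(), 2L,
                       data.frame(series = character(), index = integer(),
                                  charge = integer())),
    "empty")
})

test_that("transition-list export round-trips all species", {
  sets <- list(
    buildTransitionSet(py39_light()), buildTransitionSet(py39_heavy()),
    buildTransitionSet(y39_light()), buildTransitionSet(y39_heavy()))
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- exportTransitionList(sets, path)
  expect_equal(nrow(tab), 24L)  # 4 species x 6 y ions
  reread <- read.csv(path)
  expect_equal(names(reread)[1:3],
               c("peptide_modified_sequence", "precursor_mz",
                 "precursor_charge"))
  # recompute m/z from the parsed species and compare to 4 d.p.
  expect_equal(round(reread$precursor_mz, 4),
               round(rep(vapply(sets, function(s) s@precursorMz,
                                numeric(1)), each = 6), 4))
  expect_equal(round(reread$fragment_mz, 4),
               round(unlist(lapply(sets, function(s) fragments(s)$mz)), 4))
  expect_error(exportTransitionList(list(), path), "empty")
})
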