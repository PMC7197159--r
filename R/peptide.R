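#' Construct a modified, optionally isotope-labeled peptide
#'
#' Builds a [ModifiedPeptide-class] from a sequence, a set of site-localized
#' modifications and a label state. The assay's target species, for example,
#' is `modifiedPeptide("EGVLYVGSK", mods = list(phospho = 5))`: the tryptic
#' Y39 peptide of alpha/beta-synuclein with phosphotyrosine at peptide
#' position 5 (protein residue Tyr-39).
#'
#' @param sequence uppercase amino-acid string over the 20 standard residues.
#' @param mods named list mapping modification names (registry keys, see
#'   [modificationRegistry()]) to 1-based positions within the peptide; a
#'   name may map to several positions.
#' @param label `"light"` or `"heavy"`. The heavy state is a
#'   \eqn{^{13}C_6,^{15}N_2} label on the C-terminal lysine (+8.0142 Da);
#'   requesting it for a peptide without a C-terminal K is an error.
#' @return a validated [ModifiedPeptide-class].
#' @examples
#' precursorMz(modifiedPeptide("EGVLYVGSK", mods = list(phospho = 5)), 2L)
#' @export
modifiedPeptide <- function(sequence, mods = list(),
                            label = c("light", "heavy")) {
  label <- match.arg(label)
  residues <- strsplit(sequence, "")[[1]]
  bad <- setdiff(residues, names(.AA_MONO))
  if (length(bad))
    stop("unknown residue letter(s) in '", sequence, "': ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  rows <- list()
  for (nm in names(mods)) {
    m <- getModification(nm)
    for (pos in mods[[nm]]) {
      if (pos < 1L || pos > length(residues))
        stop("modification '", nm, "' position ", pos,
             " outside 1..", length(residues), call. = FALSE)
      if (!(residues[pos] %in% m@siteSpec))
        stop("modification '", nm, "' cannot occupy residue ",
             residues[pos], " at position ", pos, call. = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        position = as.integer(pos), name = nm, deltaMass = m@deltaMass)
    }
  }
  moddf <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(), name = character(),
               deltaMass = numeric())
  if (label == "heavy" && residues[length(residues)] != "K")
    stop("heavy label requires a C-terminal K; '", sequence,
         "' ends in ", residues[length(residues)], call. = FALSE)
  new("ModifiedPeptide", sequence = sequence, mods = moddf, label = label)
}

## Per-residue mass vector including site-localized modification deltas and,
## for heavy peptides, the label delta on the C-terminal K. Everything
## downstream (neutral mass, b/y series) derives from this one vector, which
## is what makes b/y complementarity hold by construction.
.residue_masses <- function(p) {
  residues <- strsplit(p@sequence, "")[[1]]
  m <- unname(.AA_MONO[residues])
  if (nrow(p@mods))
    for (i in seq_len(nrow(p@mods)))
      m[p@mods$position[i]] <- m[p@mods$position[i]] + p@mods$deltaMass[i]
  if (p@label == "heavy")
    m[length(m)] <- m[length(m)] + .MASS_HEAVY_K
  m
}

#' Monoisotopic neutral mass of a modified peptide
#'
#' Sum of residue monoisotopic masses plus one water, plus all modification
#' deltas, plus the heavy-label delta (+8.0142 Da on the C-terminal K) for
#' heavy peptides.
#'
#' @param p a [ModifiedPeptide-class].
#' @return neutral monoisotopic mass in Da.
#' @examples
#' peptideNeutralMass(modifiedPeptide("G"))  # 75.03203
#' @export
setMethod("peptideNeutralMass", "ModifiedPeptide", function(p) {
  sum(.residue_masses(p)) + .MASS_WATER
})

#' Precursor m/z of a modified peptide
#'
#' `(neutral mass + charge x 1.007276466) / charge`. For the Y39 assay this
#' reproduces the four monitored precursors: 516.244 (pY39 light z=2),
#' 520.251 (pY39 heavy), 476.261 (Y39 light), 480.268 (Y39 heavy).
#' Full precision is returned; round only for presentation.
#'
#' @param p a [ModifiedPeptide-class].
#' @param charge precursor charge, >= 1.
#' @return precursor m/z in Th.
#' @examples
#' p <- modifiedPeptide("EGVLYVGSK", mods = list(phospho = 5))
#' round(precursorMz(p, 2L), 3)  # 516.244
#' @export
setMethod("precursorMz", "ModifiedPeptide", function(p, charge = 2L) {
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L)
    stop("'charge' must be a positive integer", call. = FALSE)
  (peptideNeutralMass(p) + charge * .MASS_PROTON) / charge
})

#' Theoretical b- or y-ion series of a modified peptide
#'
#' Computes singly or multiply protonated b or y fragment ions
#' \eqn{b_1..b_{n-1}} / \eqn{y_1..y_{n-1}}. A y-ion carries the modification
#' deltas of its k C-terminal residues, so for EGVLpYVGSK the phospho delta
#' appears in y5..y8 but not y1..y4; the heavy-lysine label appears in every
#' y ion and in no b ion.
#'
#' @param p a [ModifiedPeptide-class].
#' @param series `"y"` or `"b"`.
#' @param charge fragment charge, >= 1.
#' @return data.frame with columns `series`, `index`, `charge`, `mz`.
#' @examples
#' fragmentSeries(modifiedPeptide("EGVLYVGSK"), "y", 1L)
#' @export
setMethod("fragmentSeries", "ModifiedPeptide",
          function(p, series = c("y", "b"), charge = 1L) {
  series <- match.arg(series)
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L)
    stop("'charge' must be a positive integer", call. = FALSE)
  m <- .residue_masses(p)
  n <- length(m)
  if (n < 2L)
    stop("fragment series require a peptide of length >= 2", call. = FALSE)
  idx <- seq_len(n - 1L)
  neutral <- if (series == "y") {
    ## y_k: k C-terminal residues + water
    cumsum(rev(m))[idx] + .MASS_WATER
  } else {
    ## b_k: k N-terminal residues (acylium, no water)
    cumsum(m)[idx]
  }
  data.frame(series = series, index = idx, charge = charge,
             mz = (neutral + charge * .MASS_PROTON) / charge)
})

#' Build the transition set monitored for one peptide species
#'
#' Materializes the precursor plus fragment ions monitored for a peptide in
#' the PRM assay. The default fragment selection is the singly charged
#' y3..y8 series — the y-ion ladder used for the 9-mer Y39 peptide, with
#' y1/y2 dropped as non-specific.
#'
#' @param p a [ModifiedPeptide-class].
#' @param precursorCharge precursor charge (default 2).
#' @param fragmentSelection data.frame with columns `series`, `index`,
#'   `charge` naming the fragments to monitor; `NULL` selects the default
#'   singly charged y3..y(n-1) (capped at y8).
#' @return a [TransitionSet-class].
#' @examples
#' ts <- buildTransitionSet(
#'   modifiedPeptide("EGVLYVGSK", mods = list(phospho = 5)))
#' round(ts@precursorMz, 3)  # 516.244
#' @export
buildTransitionSet <- function(p, precursorCharge = 2L,
                               fragmentSelection = NULL) {
  n <- nchar(p@sequence)
  if (is.null(fragmentSelection)) {
    hi <- min(n - 1L, 8L)
    if (hi < 3L)
      stop("peptide too short for the default y3..y8 selection", call. = FALSE)
    fragmentSelection <- data.frame(series = "y", index = 3:hi, charge = 1L)
  }
  if (nrow(fragmentSelection) == 0L)
    stop("empty fragment selection", call. = FALSE)
  if (any(fragmentSelection$index >= n))
    stop("fragment index must be < peptide length (", n, ")", call. = FALSE)
  frag <- do.call(rbind, lapply(
    split(fragmentSelection,
          paste(fragmentSelection$series, fragmentSelection$charge)),
    function(sel) {
      full <- fragmentSeries(p, sel$series[1], sel$charge[1])
      full[full$index %in% sel$index, ]
    }))
  frag <- frag[order(frag$series, frag$index, frag$charge), ]
  rownames(frag) <- NULL
  new("TransitionSet", peptide = p,
      precursorMz = precursorMz(p, precursorCharge),
      precursorCharge = as.integer(precursorCharge), fragments = frag)
}

## Skyline-style modified-sequence notation, e.g. EGVLY[+80.0]VGSK.
.modified_notation <- function(p) {
  residues <- strsplit(p@sequence, "")[[1]]
  out <- residues
  if (nrow(p@mods))
    for (i in seq_len(nrow(p@mods))) {
      pos <- p@mods$position[i]
      out[pos] <- sprintf("%s[%+0.1f]", out[pos], p@mods$deltaMass[i])
    }
  paste0(paste(out, collapse = ""), if (p@label == "heavy") " (heavy)" else "")
}

#' Export a transition list as CSV
#'
#' Writes one row per (species, fragment) with the fixed column order
#' `peptide_modified_sequence, precursor_mz, precursor_charge,
#' fragment_name, fragment_mz, fragment_charge, label_state` — a shape
#' importable into targeted-proteomics tools.
#'
#' @param sets non-empty list of [TransitionSet-class] objects.
#' @param path output file path.
#' @return the exported data.frame, invisibly.
#' @export
exportTransitionList <- function(sets, path) {
  if (length(sets) == 0L)
    stop("empty transition-set list", call. = FALSE)
  tab <- do.call(rbind, lapply(sets, function(ts) {
    fr <- ts@fragments
    data.frame(
      peptide_modified_sequence = .modified_notation(ts@peptide),
      precursor_mz = ts@precursorMz,
      precursor_charge = ts@precursorCharge,
      fragment_name = sprintf("%s%d", fr$series, fr$index),
      fragment_mz = fr$mz,
      fragment_charge = fr$charge,
      label_state = ts@peptide@label)
  }))
  rownames(tab) <- NULL
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  invisible(tab)
}

#' @export
setMethod("show", "ModifiedPeptide", function(object) {
  cat(sprintf("ModifiedPeptide %s [%s]", .modified_notation(object),
              object@label))
  cat(sprintf(", neutral mass %.5f Da\n", peptideNeutralMass(object)))
})

#' @export
setMethod("show", "TransitionSet", function(object) {
  cat(sprintf("TransitionSet %s: precursor %.4f Th (z=%d), %d fragment(s)\n",
              .modified_notation(object@peptide), object@precursorMz,
              object@precursorCharge, nrow(object@fragments)))
})
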