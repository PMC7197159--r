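## Built-in modification registry.

.mod_registry <- new.env(parent = emptyenv())

.register_builtin_mods <- function() {
  builtin <- list(
    new("Modification", name = "phospho", deltaMass = 79.96633,
        siteSpec = c("S", "T", "Y")),
    new("Modification", name = "carbamidomethyl", deltaMass = 57.02146,
        siteSpec = "C"),
    ## 13C6,15N2-lysine, the heavy-standard label
    new("Modification", name = "heavyK", deltaMass = .MASS_HEAVY_K,
        siteSpec = "K")
  )
  for (m in builtin) assign(m@name, m, envir = .mod_registry)
}

#' Modification registry
#'
#' The package keeps a registry of named mass modifications. The built-ins
#' cover the synuclein Y39 assay: `phospho` (+79.96633 Da on S/T/Y),
#' `carbamidomethyl` (+57.02146 Da on C, from iodoacetamide alkylation;
#' available but never auto-applied) and `heavyK` (+8.0142 Da, the
#' \eqn{^{13}C_6,^{15}N_2}-lysine stable-isotope label used for heavy
#' internal standards). `registerModification()` adds user-defined entries,
#' e.g. from an assay configuration file.
#'
#' @param name modification name (registry key).
#' @param deltaMass monoisotopic mass shift in Da.
#' @param siteSpec residue letters (or `"N-term"`/`"C-term"`) the
#'   modification may occupy.
#' @return `modificationRegistry()` returns a named list of
#'   [Modification-class] objects; `getModification()` a single one;
#'   `registerModification()` (invisibly) the object it registered.
#' @examples
#' names(modificationRegistry())
#' getModification("phospho")@deltaMass
#' @export
modificationRegistry <- function() {
  as.list(.mod_registry)
}

#' @rdname modificationRegistry
#' @export
getModification <- function(name) {
  if (!exists(name, envir = .mod_registry, inherits = FALSE))
    stop("unknown modification: '", name, "' (see modificationRegistry())",
         call. = FALSE)
  get(name, envir = .mod_registry, inherits = FALSE)
}

#' @rdname modificationRegistry
#' @export
registerModification <- function(name, deltaMass, siteSpec) {
  m <- new("Modification", name = name, deltaMass = deltaMass,
           siteSpec = siteSpec)
  assign(name, m, envir = .mod_registry)
  invisible(m)
}

#' @export
setMethod("show", "Modification", function(object) {
  cat(sprintf("Modification '%s': %+0.5f Da on %s\n", object@name,
              object@deltaMass, paste(object@siteSpec, collapse = "/")))
})
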