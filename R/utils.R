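#' @keywords internal
"_PACKAGE"

# Controlled vocabularies used across the package -----------------------------

#' PTM types recognized by the package
#'
#' The eight post-translational modification classes tracked by the pipeline:
#' hydroxylation, phosphorylation, N- and O-glycosylation, acetylation,
#' ubiquitylation, sumoylation, and methylation.
#'
#' @return Character vector of PTM type identifiers.
#' @export
ptm_types <- function() {
  c("hydroxylation", "phosphorylation", "n_glycosylation", "o_glycosylation",
    "acetylation", "ubiquitylation", "sumoylation", "methylation")
}

#' Chemically valid target residues for each PTM type
#'
#' Hydroxylation targets proline/lysine (collagen chemistry), N-glycosylation
#' targets asparagine, O-glycosylation serine/threonine, phosphorylation
#' serine/threonine/tyrosine, and the lysine-directed modifications
#' (acetylation, ubiquitylation, sumoylation) target lysine; methylation
#' targets lysine or arginine.
#'
#' @return Named list mapping PTM type to a character vector of one-letter
#'   amino-acid codes.
#' @export
ptm_valid_residues <- function() {
  list(
    hydroxylation   = c("P", "K"),
    phosphorylation = c("S", "T", "Y"),
    n_glycosylation = "N",
    o_glycosylation = c("S", "T"),
    acetylation     = "K",
    ubiquitylation  = "K",
    sumoylation     = "K",
    methylation     = c("K", "R")
  )
}

#' Matrisome divisions and categories
#'
#' The matrisome is split into the core matrisome (collagens, ECM
#' glycoproteins, proteoglycans) and matrisome-associated proteins
#' (ECM-affiliated proteins, ECM regulators, secreted factors).
#'
#' @return Named character vector mapping category to division.
#' @export
matrisome_categories <- function() {
  c(collagens         = "core_matrisome",
    ecm_glycoproteins = "core_matrisome",
    proteoglycans     = "core_matrisome",
    ecm_affiliated    = "matrisome_associated",
    ecm_regulators    = "matrisome_associated",
    secreted_factors  = "matrisome_associated")
}

mutation_effects <- function() {
  c("missense", "nonsense", "frameshift", "inframe_indel", "splice_site",
    "silent", "other_nonsilent")
}

amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Deterministic child-seed derivation: every stage of the pipeline draws from
# its own stream so module-level reruns match full pipeline runs.  Values stay
# below 2^31 - 1 (R integers are 32-bit).
stage_seed <- function(seed, stage) {
  as.integer(((as.numeric(seed) %% 1000003) * 1009 + stage * 101) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
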