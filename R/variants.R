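#' The 20 standard amino acids, one-letter code, alphabetical
#'
#' @format Character vector of length 20.
#' @export
AMINO_ACIDS <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' Enumerate the complete CXXX sequence space
#'
#' The CaaX-type library holds a fixed N-terminal cysteine followed by three
#' fully randomised positions, giving 20^3 = 8,000 tetrapeptides. Enumeration
#' is lexicographic over the standard one-letter alphabet so that output
#' ordering is byte-stable across runs and platforms.
#'
#' @return A tibble with one row per variant and a single column `variant`
#'   (4-character string beginning with "C"), in lexicographic order.
#' @examples
#' v <- cxxx_variants()
#' nrow(v)          # 8000
#' v$variant[1]     # "CAAA"
#' @export
cxxx_variants <- function() {
  grid <- expand.grid(
    x3 = AMINO_ACIDS, x2 = AMINO_ACIDS, x1 = AMINO_ACIDS,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  tibble::tibble(variant = paste0("C", grid$x1, grid$x2, grid$x3))
}

# Biostrings coercions warn when they drop (empty) metadata columns; that
# warning is noise at this call depth.
muffle_metadata_warning <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("metadata columns", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

#' Translate the 9-nt variable region of a library amplicon
#'
#' Applies the standard nuclear genetic code to the three variable codons of
#' the library insert. Sequences that cannot represent a library member are
#' rejected rather than translated: a stop codon anywhere in the region
#' ("stop_codon"), a non-ACGT character ("bad_base"), or a length other than
#' nine ("bad_length").
#'
#' @param dna Character vector of candidate 9-nt sequences (case-insensitive).
#' @return A tibble with columns `dna`, `protein` (3-residue translation, `NA`
#'   when rejected) and `status` (`"ok"` or the rejection reason).
#' @examples
#' translate_variable_region(c("GTTTTGTTG", "TAATTGTTG", "GTNTTGTTG"))
#' @export
translate_variable_region <- function(dna) {
  up <- toupper(dna)
  status <- rep("ok", length(up))
  status[nchar(up) != 9L] <- "bad_length"
  ok_len <- status == "ok"
  bad_base <- ok_len & grepl("[^ACGT]", up)
  status[bad_base] <- "bad_base"

  protein <- rep(NA_character_, length(up))
  todo <- status == "ok"
  if (any(todo)) {
    aa <- as.character(muffle_metadata_warning(
      Biostrings::translate(Biostrings::DNAStringSet(up[todo]),
                            genetic.code = Biostrings::GENETIC_CODE)
    ))
    has_stop <- grepl("\\*", aa, fixed = FALSE)
    status[todo][has_stop] <- "stop_codon"
    protein[todo][!has_stop] <- aa[!has_stop]
  }
  tibble::tibble(dna = as.character(dna), protein = protein, status = status)
}

#' Residue sets defining the motif-classification rules
#'
#' The default sets encode the consensus the screen itself supports: a
#' hydrophobic consensus X residue (L/F/I/M/V), a branched-chain aliphatic
#' (BCA) a2 residue (V/I/L) required by the Rce1 CaaX protease, and the
#' residues reported to block prenylation of the reporter (charged a2 D/E/K/R;
#' X of K/R/P). All sets can be overridden to probe alternative consensus
#' definitions.
#'
#' @param x_consensus Residues accepted at the terminal X position.
#' @param a2_bca Branched-chain aliphatic residues accepted at a2.
#' @param restrictive_a2 a2 residues treated as prenylation-blocking.
#' @param restrictive_x X residues treated as prenylation-blocking.
#' @return A named list of residue sets with class `caax_ruleset`.
#' @export
caax_ruleset <- function(x_consensus = c("L", "F", "I", "M", "V"),
                         a2_bca = c("V", "I", "L"),
                         restrictive_a2 = c("D", "E", "K", "R"),
                         restrictive_x = c("K", "R", "P")) {
  sets <- list(
    x_consensus = x_consensus, a2_bca = a2_bca,
    restrictive_a2 = restrictive_a2, restrictive_x = restrictive_x
  )
  bad <- !vapply(sets, function(s) all(s %in% AMINO_ACIDS), logical(1))
  if (any(bad)) {
    rlang::abort(paste0(
      "ruleset sets must use standard one-letter amino acids; offending: ",
      paste(names(sets)[bad], collapse = ", ")
    ))
  }
  structure(sets, class = "caax_ruleset")
}

#' Map each amino acid to its logo colour class
#'
#' The five classes used throughout logo rendering and composition reports:
#' cysteine on its own; branched-chain aliphatics (V/I/L); charged residues
#' (K/R/H/D/E); polar uncharged residues (S/Q/T/N); and the remaining
#' hydrophobics (A/G/P/F/W/Y/M). The classes partition the 20 amino acids.
#'
#' @param residues Character vector of one-letter residues (default: all 20).
#' @return A tibble with columns `residue` and `class`.
#' @export
residue_classes <- function(residues = AMINO_ACIDS) {
  cls <- function(r) {
    if (r == "C") "cysteine"
    else if (r %in% c("V", "I", "L")) "branched_aliphatic"
    else if (r %in% c("K", "R", "H", "D", "E")) "charged"
    else if (r %in% c("S", "Q", "T", "N")) "polar_uncharged"
    else "other_hydrophobic"
  }
  tibble::tibble(
    residue = as.character(residues),
    class = vapply(as.character(residues), cls, character(1), USE.NAMES = FALSE)
  )
}

#' Classify CXXX motifs against the consensus and restrictive-residue rules
#'
#' Adds per-variant boolean flags: `x_consensus` (terminal residue in the
#' consensus X set), `a2_bca` (a2 is branched-chain aliphatic, the Rce1
#' cleavage requirement), `canonical_cleavable` (both of the above, i.e. the
#' Cx[V/I/L][L/F/I/M/V] profile expected to be prenylated *and* proteolysed),
#' and `restrictive` (a2 or X carries a residue reported to block prenylation
#' of the reporter). The a1 position is deliberately unconstrained: sequences
#' such as CAIL behave canonically in the screen despite a non-aliphatic a1.
#'
#' @param data A data frame with a column of 4-residue variants.
#' @param ruleset A [caax_ruleset()].
#' @param variant_col Name of the variant column. Default `"variant"`.
#' @return `data` with the four logical flag columns appended.
#' @examples
#' classify_motifs(tibble::tibble(variant = c("CVLL", "CSFL", "CARL")))
#' @export
classify_motifs <- function(data, ruleset = caax_ruleset(),
                            variant_col = "variant") {
  stopifnot(is.data.frame(data), variant_col %in% names(data))
  v <- data[[variant_col]]
  if (any(nchar(v) != 4L | substr(v, 1, 1) != "C")) {
    rlang::abort("variants must be 4-character strings starting with 'C'")
  }
  a2 <- substr(v, 3, 3)
  x <- substr(v, 4, 4)
  out <- dplyr::mutate(
    tibble::as_tibble(data),
    x_consensus = x %in% ruleset$x_consensus,
    a2_bca = a2 %in% ruleset$a2_bca,
    canonical_cleavable = .data$a2_bca & .data$x_consensus,
    restrictive = a2 %in% ruleset$restrictive_a2 | x %in% ruleset$restrictive_x
  )
  out
}
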