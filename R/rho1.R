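# Colony-screen analysis: the deduplication ladder (raw picks -> non-parent
# -> unique DNA -> distinct proteins), consensus splitting, and
# cross-referencing of hits against the thermotolerance E-Scores.

#' Deduplicate colony-screen DNA sequences
#'
#' Applies the screen's deduplication ladder to a list of 9-nt variable-region
#' sequences recovered from survivor colonies: (1) remove picks identical to
#' the parent (wild-type) DNA, which arise from gene conversion with the
#' resident plasmid; (2) collapse exact DNA duplicates, which arise from
#' double-picked colonies; (3) translate the survivors and collapse
#' synonymous encodings to distinct protein variants (the fixed cysteine is
#' prepended). Untranslatable sequences (stop codon, bad base, bad length)
#' are listed as rejects and excluded from every count.
#'
#' @param dna_list Character vector of 9-nt DNA sequences (one per colony).
#' @param parent_dna The parent's 9-nt variable-region sequence.
#' @return An object of class `dedup_report`: a list with `report` (one-row
#'   tibble of the ladder counts), `variants` (tibble `variant`,
#'   `n_encodings` — codon-level multiplicity per distinct protein), `unique_dna`
#'   (character vector) and `rejects` (tibble `dna`, `status`). Ladder
#'   identities: `n_remaining = n_input - n_parent_identical`;
#'   `n_unique_dna = n_remaining - n_duplicate_dna`;
#'   `n_distinct_protein <= n_unique_dna`.
#' @seealso [tidy.dedup_report()], [glance.dedup_report()]
#' @export
dedup_hits <- function(dna_list, parent_dna) {
  dna_list <- toupper(as.character(dna_list))
  parent_dna <- toupper(parent_dna)
  # untranslatable picks (sequencing artefacts) leave the ladder up front so
  # the ladder identities hold exactly over what remains
  tr_all <- translate_variable_region(dna_list)
  rejects <- tibble::tibble(dna = tr_all$dna[tr_all$status != "ok"],
                            status = tr_all$status[tr_all$status != "ok"])
  kept <- tr_all[tr_all$status == "ok", ]
  n_input <- nrow(kept)
  is_parent <- kept$dna == parent_dna
  remaining <- kept[!is_parent, ]
  n_parent <- sum(is_parent)
  # exact DNA duplicates among the non-parent picks
  dup <- duplicated(remaining$dna)
  ok <- remaining[!dup, ]
  n_dup <- sum(dup)
  n_unique_dna <- nrow(ok)
  variants <- if (n_unique_dna > 0) {
    tibble::tibble(variant = paste0("C", ok$protein)) |>
      dplyr::count(.data$variant, name = "n_encodings") |>
      dplyr::arrange(.data$variant)
  } else {
    tibble::tibble(variant = character(), n_encodings = integer())
  }
  report <- tibble::tibble(
    n_input = n_input,
    n_parent_identical = n_parent,
    n_remaining = n_input - n_parent,
    n_duplicate_dna = n_dup,
    n_unique_dna = n_unique_dna,
    n_rejected = nrow(rejects),
    n_distinct_protein = nrow(variants)
  )
  structure(
    list(report = report, variants = variants, unique_dna = ok$dna,
         rejects = rejects),
    class = "dedup_report"
  )
}

#' @export
print.dedup_report <- function(x, ...) {
  r <- x$report
  cat("Colony-screen deduplication ladder\n")
  cat(sprintf("  picks:               %d\n", r$n_input))
  cat(sprintf("  parent-identical:    %d (gene conversion)\n",
              r$n_parent_identical))
  cat(sprintf("  remaining:           %d\n", r$n_remaining))
  cat(sprintf("  duplicate DNA:       %d (double picks)\n", r$n_duplicate_dna))
  cat(sprintf("  unique DNA:          %d\n", r$n_unique_dna))
  if (r$n_rejected > 0) {
    cat(sprintf("  rejected (untranslatable): %d\n", r$n_rejected))
  }
  cat(sprintf("  distinct proteins:   %d\n", r$n_distinct_protein))
  invisible(x)
}

#' Tidy a deduplication report: one row per distinct protein variant
#'
#' @param x A [dedup_hits()] result.
#' @param ... Ignored.
#' @return Tibble with columns `variant` and `n_encodings`.
#' @export
tidy.dedup_report <- function(x, ...) x$variants

#' One-row summary of a deduplication report
#'
#' @param x A [dedup_hits()] result.
#' @param ... Ignored.
#' @return The one-row ladder tibble.
#' @export
glance.dedup_report <- function(x, ...) x$report

#' Cross-reference hit variants against an E-Score table
#'
#' Bins a list of hit variants by their E-Score in a reference table. The
#' default edges reproduce the report's reading of the score distribution:
#' enriched above 2, intermediate in [0.5, 2], de-enriched below 0.5;
#' variants with an undefined score or absent from the score universe are
#' tallied separately so the bin counts always sum to the list size.
#'
#' @param variant_list Character vector (or data frame with a `variant`
#'   column) of hit variants.
#' @param escores An E-Score table (see [compute_escores()]).
#' @param lower,upper Bin edges (defaults 0.5 and 2).
#' @return Tibble with columns `bin` (`">2"`, `"[0.5,2]"`, `"<0.5"`,
#'   `"undefined"`, `"not_in_universe"`), `n`, `fraction` (of the list size).
#' @export
crossref_escores <- function(variant_list, escores, lower = 0.5, upper = 2) {
  if (is.data.frame(variant_list)) variant_list <- variant_list$variant
  variant_list <- as.character(variant_list)
  n_total <- length(variant_list)
  lookup <- stats::setNames(escores$escore, escores$variant)
  known <- variant_list %in% names(lookup)
  score <- lookup[variant_list[known]]
  bins <- c(paste0(">", upper), paste0("[", lower, ",", upper, "]"),
            paste0("<", lower), "undefined", "not_in_universe")
  counts <- c(
    sum(!is.na(score) & score > upper),
    sum(!is.na(score) & score >= lower & score <= upper),
    sum(!is.na(score) & score < lower),
    sum(is.na(score)),
    sum(!known)
  )
  tibble::tibble(
    bin = bins, n = as.integer(counts),
    fraction = if (n_total > 0) counts / n_total else rep(0, length(counts))
  )
}

#' Split hit variants on the consensus X residue
#'
#' Partitions a variant list into sequences conforming to the CXX[L/F/I/M/V]
#' consensus (consensus X residue) and those not conforming, the two subsets
#' fed to separate logo analyses.
#'
#' @param variant_list Character vector or data frame with a `variant`
#'   column.
#' @param ruleset A [caax_ruleset()].
#' @return Named list of two character vectors, `conforming` and
#'   `nonconforming`.
#' @examples
#' split_by_consensus(c("CVLL", "CVLQ"))
#' @export
split_by_consensus <- function(variant_list, ruleset = caax_ruleset()) {
  if (is.data.frame(variant_list)) variant_list <- variant_list$variant
  if (length(variant_list) == 0) {
    return(list(conforming = character(), nonconforming = character()))
  }
  cls <- classify_motifs(tibble::tibble(variant = variant_list),
                         ruleset = ruleset)
  list(
    conforming = cls$variant[cls$x_consensus],
    nonconforming = cls$variant[!cls$x_consensus]
  )
}
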