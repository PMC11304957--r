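# Logo-style position frequency matrices, consensus strings and composition
# reports over variant subsets.

#' Build a position frequency matrix from a variant subset
#'
#' The PFM of a subset is, per position, the fraction of subset members
#' carrying each residue — the numeric content of a frequency-scaled sequence
#' logo. Frequencies (not information bits) are used throughout. The
#' invariant position-1 cysteine can be kept or dropped.
#'
#' @param variants Character vector of equal-length sequences, or a data
#'   frame with a `variant` column.
#' @param drop_first_c Drop position 1 (the fixed cysteine) from the matrix.
#' @return A long tibble with columns `position`, `residue`, `frequency`
#'   (class `caax_pfm`), with attribute `"n"` (subset size). Every residue is
#'   present at every position (zero rows included), so each position's
#'   frequencies sum to 1.
#' @examples
#' build_pfm(c("CVLL", "CVIL"))
#' @export
build_pfm <- function(variants, drop_first_c = FALSE) {
  if (is.data.frame(variants)) variants <- variants$variant
  if (length(variants) == 0) rlang::abort("empty subset")
  len <- unique(nchar(variants))
  if (length(len) != 1) rlang::abort("sequences must have equal length")
  n <- length(variants)
  m <- do.call(rbind, strsplit(variants, "", fixed = TRUE))
  positions <- seq_len(len)
  if (drop_first_c) positions <- positions[-1]
  out <- purrr::map_dfr(positions, function(p) {
    counts <- table(factor(m[, p], levels = AMINO_ACIDS))
    tibble::tibble(position = p, residue = AMINO_ACIDS,
                   frequency = as.numeric(counts) / n)
  })
  attr(out, "n") <- n
  class(out) <- c("caax_pfm", class(out))
  out
}

#' Annotate a PFM with the five residue colour classes
#'
#' @param pfm A [build_pfm()] result.
#' @return The PFM with a `class` column appended (see [residue_classes()]).
#' @export
annotate_classes <- function(pfm) {
  out <- dplyr::left_join(pfm, residue_classes(), by = "residue")
  attr(out, "n") <- attr(pfm, "n")
  class(out) <- unique(c("caax_pfm", class(out)))
  out
}

#' Degenerate consensus string from a PFM
#'
#' Per position, emits the smallest residue set (ordered by descending
#' frequency, ties broken alphabetically) whose cumulative frequency reaches
#' `majority_threshold`. Sets of one residue print as the residue, larger
#' sets as `[A/B/...]`, and positions needing more than `max_set` residues
#' print as `x` (no useful preference).
#'
#' @param pfm A [build_pfm()] result.
#' @param majority_threshold Cumulative frequency the set must reach, in
#'   (0, 1].
#' @param max_set Largest residue set rendered explicitly.
#' @return A single consensus string, e.g. `"Cx[V/I/L][L/F/I/M/V]"`.
#' @export
consensus_string <- function(pfm, majority_threshold = 0.9, max_set = 5) {
  stopifnot(majority_threshold > 0, majority_threshold <= 1)
  pieces <- pfm |>
    dplyr::group_by(.data$position) |>
    dplyr::group_map(function(df, key) {
      df <- dplyr::arrange(df, dplyr::desc(.data$frequency), .data$residue)
      cum <- cumsum(df$frequency)
      k <- which(cum >= majority_threshold - 1e-12)[1]
      if (is.na(k) || k > max_set) return("x")
      set <- df$residue[seq_len(k)]
      if (length(set) == 1) set else paste0("[", paste(set, collapse = "/"), "]")
    })
  paste(unlist(pieces), collapse = "")
}

#' Motif-composition report for a variant subset
#'
#' Counts and fractions of the subset carrying each motif flag: the
#' consensus X residue, a branched-chain aliphatic a2, the full canonical
#' cleavable profile, a restrictive residue, or none of these.
#'
#' @param variants Character vector or data frame with a `variant` column.
#' @param ruleset A [caax_ruleset()].
#' @return Tibble with columns `flag`, `n`, `fraction`. Flags are not
#'   mutually exclusive (canonical implies x_consensus); `none` counts
#'   variants matching no flag.
#' @examples
#' composition_stats(c("CVLL", "CSFL", "CARL"))
#' @export
composition_stats <- function(variants, ruleset = caax_ruleset()) {
  if (!is.data.frame(variants)) {
    variants <- tibble::tibble(variant = variants)
  }
  if (nrow(variants) == 0) rlang::abort("empty subset")
  cls <- classify_motifs(variants, ruleset = ruleset)
  n_total <- nrow(cls)
  none <- !cls$x_consensus & !cls$a2_bca & !cls$restrictive
  counts <- c(sum(cls$x_consensus), sum(cls$a2_bca),
              sum(cls$canonical_cleavable), sum(cls$restrictive), sum(none))
  tibble::tibble(
    flag = c("x_consensus", "a2_bca", "canonical_cleavable", "restrictive",
             "none"),
    n = counts,
    fraction = counts / n_total
  )
}

#' Frequency logo plot of a PFM
#'
#' Renders the PFM as stacked per-position residue letters scaled by
#' frequency, coloured by the five residue classes used in the screen's
#' logos: cysteine blue, branched-chain aliphatics red, charged residues
#' green, polar uncharged black, other hydrophobics purple.
#'
#' @param object A [build_pfm()] result.
#' @param min_frequency Residues below this frequency are not drawn.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.caax_pfm <- function(object, min_frequency = 0.02, ...) {
  palette <- c(cysteine = "#1f4ea1", branched_aliphatic = "#c0272d",
               charged = "#1e8a3c", polar_uncharged = "#000000",
               other_hydrophobic = "#7b2d8b")
  df <- annotate_classes(object) |>
    dplyr::filter(.data$frequency >= min_frequency) |>
    dplyr::group_by(.data$position) |>
    dplyr::arrange(.data$frequency, .by_group = TRUE) |>
    dplyr::mutate(ymax = cumsum(.data$frequency),
                  ymid = .data$ymax - .data$frequency / 2) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$ymid)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$residue,
                                    size = .data$frequency,
                                    colour = .data$class),
                       fontface = "bold", show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = palette) +
    ggplot2::scale_size_continuous(range = c(2, 10)) +
    ggplot2::scale_x_continuous(breaks = sort(unique(df$position))) +
    ggplot2::labs(x = "position", y = "cumulative frequency")
}

#' @rdname autoplot.caax_pfm
#' @param pfm A [build_pfm()] result.
#' @export
plot_logo <- function(pfm, min_frequency = 0.02) {
  autoplot.caax_pfm(pfm, min_frequency = min_frequency)
}
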