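# Frequencies, NGS E-Scores and subset selection: the screen's core statistic.

#' Compute per-variant frequencies for one library
#'
#' The frequency of a variant is its total count, summed over all replicates,
#' divided by the sum of all validated variant counts in the library — i.e.
#' rejected reads never enter the denominator. When an expected universe is
#' supplied (normally the full 8,000-variant enumeration), unobserved variants
#' are reported with frequency zero so that every library shares one variant
#' universe.
#'
#' @param counts Either a merged long count table (see [merge_replicates()]),
#'   any data frame with `variant` and `count` columns, or a data frame with
#'   `variant` and `total`.
#' @param universe Optional data frame with a `variant` column defining the
#'   expected variant universe.
#' @param library_id Library label carried through to the result.
#' @return Tibble with columns `variant`, `total`, `frequency`, sorted by
#'   variant; attribute `"library_id"`.
#' @examples
#' compute_frequencies(tibble::tibble(variant = c("CAAA", "CAAC"),
#'                                    count = c(4L, 6L)))
#' @export
compute_frequencies <- function(counts, universe = NULL,
                                library_id = attr(counts, "library_id")) {
  stopifnot(is.data.frame(counts))
  if ("total" %in% names(counts) && !"count" %in% names(counts)) {
    totals <- dplyr::select(tibble::as_tibble(counts), "variant", "total")
  } else {
    stopifnot(all(c("variant", "count") %in% names(counts)))
    totals <- counts |>
      dplyr::group_by(.data$variant) |>
      dplyr::summarise(total = sum(.data$count), .groups = "drop")
  }
  if (!is.null(universe)) {
    totals <- tibble::tibble(variant = universe$variant) |>
      dplyr::left_join(totals, by = "variant") |>
      dplyr::mutate(total = dplyr::coalesce(.data$total, 0L))
  }
  grand <- sum(as.numeric(totals$total))
  if (grand <= 0) rlang::abort("all counts are zero; cannot compute frequencies")
  out <- totals |>
    dplyr::mutate(frequency = .data$total / grand) |>
    dplyr::arrange(.data$variant)
  attr(out, "library_id") <- library_id %||% "library"
  out
}

#' Compute NGS enrichment scores (E-Scores)
#'
#' The E-Score of a variant is its frequency in a selected library divided by
#' its frequency in the naive library. Scores above 1 indicate enrichment
#' under selection, below 1 de-enrichment; a zero numerator gives a score of
#' exactly 0. A zero naive frequency leaves the score undefined — such
#' variants are flagged (`status = "undefined"`), excluded from rankings, and
#' reported with a warning, never smoothed with pseudocounts.
#'
#' @param selected Frequency table for the selected library
#'   (see [compute_frequencies()]).
#' @param naive Frequency table for the naive library over the same variant
#'   universe.
#' @return Tibble with columns `variant`, `freq_naive`, `freq_selected`,
#'   `escore` (`NA` when undefined) and `status`
#'   (`"enriched"`, `"de-enriched"`, `"neutral"`, `"undefined"`); attributes
#'   `"numerator_library_id"` and `"denominator_library_id"`.
#' @export
compute_escores <- function(selected, naive) {
  stopifnot(is.data.frame(selected), is.data.frame(naive),
            all(c("variant", "frequency") %in% names(selected)),
            all(c("variant", "frequency") %in% names(naive)))
  if (!setequal(selected$variant, naive$variant)) {
    rlang::abort("selected and naive tables must share one variant universe")
  }
  joined <- dplyr::inner_join(
    dplyr::select(naive, "variant", freq_naive = "frequency"),
    dplyr::select(selected, "variant", freq_selected = "frequency"),
    by = "variant"
  )
  out <- joined |>
    dplyr::mutate(
      escore = dplyr::if_else(.data$freq_naive > 0,
                              .data$freq_selected / .data$freq_naive,
                              NA_real_),
      status = dplyr::case_when(
        is.na(.data$escore) ~ "undefined",
        .data$escore > 1 ~ "enriched",
        .data$escore < 1 ~ "de-enriched",
        TRUE ~ "neutral"
      )
    ) |>
    dplyr::arrange(.data$variant)
  n_undef <- sum(out$status == "undefined")
  if (n_undef > 0) {
    rlang::warn(paste0(n_undef, " variant(s) absent from the naive library; ",
                       "their E-Scores are undefined and excluded from rankings"))
  }
  attr(out, "numerator_library_id") <- attr(selected, "library_id")
  attr(out, "denominator_library_id") <- attr(naive, "library_id")
  out
}

#' Select variants by an E-Score threshold
#'
#' Returns all variants with a defined score satisfying the comparison, in a
#' deterministic order (score, then variant lexicographically).
#'
#' @param escores An E-Score table (see [compute_escores()]).
#' @param cutoff Numeric threshold.
#' @param comparator One of `"<"`, `"<="`, `">"`, `">="`.
#' @return Tibble of the selected rows.
#' @examples
#' es <- tibble::tibble(variant = c("CAAA", "CAAC"),
#'                      escore = c(0.1, 0.3),
#'                      status = c("de-enriched", "de-enriched"))
#' select_by_threshold(es, 0.2, "<")
#' @export
select_by_threshold <- function(escores, cutoff,
                                comparator = c("<", "<=", ">", ">=")) {
  comparator <- match.arg(comparator)
  cmp <- match.fun(comparator)
  escores |>
    dplyr::filter(!is.na(.data$escore), cmp(.data$escore, cutoff)) |>
    dplyr::arrange(.data$escore, .data$variant)
}

#' Select the top (or bottom) n variants by E-Score
#'
#' Ties at the selection boundary are broken lexicographically by variant so
#' the subset is stable across runs.
#'
#' @param escores An E-Score table.
#' @param n Number of variants to select (positive, at most the number of
#'   defined scores).
#' @param direction `"top"` (largest scores first) or `"bottom"`.
#' @return Tibble of the `n` selected rows, in selection order.
#' @export
select_top_n <- function(escores, n, direction = c("top", "bottom")) {
  direction <- match.arg(direction)
  if (n <= 0) rlang::abort("n must be positive")
  defined <- dplyr::filter(escores, !is.na(.data$escore))
  if (n > nrow(defined)) {
    rlang::abort("n exceeds the number of defined E-Scores")
  }
  ordered <- if (direction == "top") {
    dplyr::arrange(defined, dplyr::desc(.data$escore), .data$variant)
  } else {
    dplyr::arrange(defined, .data$escore, .data$variant)
  }
  utils::head(ordered, n)
}

#' Paired frequency table for naive-vs-condition scatter plots
#'
#' One row per universe variant with its naive frequency (x), the selected
#' condition's frequency (y), and the E-Score.
#'
#' @param freq_naive,freq_selected Frequency tables over a shared universe.
#' @return Tibble with columns `variant`, `freq_naive`, `freq_selected`,
#'   `escore`, `status`.
#' @export
export_scatter <- function(freq_naive, freq_selected) {
  suppressWarnings(compute_escores(freq_selected, freq_naive))
}

#' Scatter plot of naive vs selected frequencies
#'
#' @param scatter Output of [export_scatter()] (or [compute_escores()]).
#' @param log_axes Use log10 axes (zero frequencies dropped from display).
#' @return A ggplot object.
#' @export
plot_frequency_scatter <- function(scatter, log_axes = FALSE) {
  p <- ggplot2::ggplot(scatter,
                       ggplot2::aes(x = .data$freq_naive,
                                    y = .data$freq_selected)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "frequency in naive library",
                  y = "frequency after selection")
  if (log_axes) {
    p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  }
  p
}

#' Summary statistics of a published-style frequency table
#'
#' Recomputes E-Scores from a supplementary-style table of per-library
#' frequencies (columns `variant`, `freq_naive`, `freq_37C`, `freq_42C`) and
#' summarises the values a reader would check first: the maximum score per
#' condition and the number of variants below a de-enrichment cutoff at 37C.
#'
#' @param freq_table Data frame with columns `variant`, `freq_naive`,
#'   `freq_37C`, `freq_42C` (frequencies on the 0-1 scale).
#' @param deenriched_cutoff Cutoff defining the strongly de-enriched 37C
#'   subset (default 0.2).
#' @return One-row tibble: `max_escore_37C`, `max_escore_42C`,
#'   `n_deenriched_37C`.
#' @export
summarise_published_escores <- function(freq_table, deenriched_cutoff = 0.2) {
  stopifnot(all(c("variant", "freq_naive", "freq_37C", "freq_42C") %in%
                  names(freq_table)))
  naive <- tibble::tibble(variant = freq_table$variant,
                          frequency = freq_table$freq_naive)
  s37 <- tibble::tibble(variant = freq_table$variant,
                        frequency = freq_table$freq_37C)
  s42 <- tibble::tibble(variant = freq_table$variant,
                        frequency = freq_table$freq_42C)
  e37 <- suppressWarnings(compute_escores(s37, naive))
  e42 <- suppressWarnings(compute_escores(s42, naive))
  tibble::tibble(
    max_escore_37C = max(e37$escore, na.rm = TRUE),
    max_escore_42C = max(e42$escore, na.rm = TRUE),
    n_deenriched_37C = nrow(select_by_threshold(e37, deenriched_cutoff, "<"))
  )
}
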