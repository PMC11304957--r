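# FASTQ -> validated per-replicate variant count tables.

# Hamming distance of s against each window of x with the same length;
# returns the first position (1-based) where distance <= max_mismatch, or NA.
find_anchor <- function(x, anchor, max_mismatch, from = 1L) {
  la <- nchar(anchor)
  lx <- nchar(x)
  if (lx < la) return(NA_integer_)
  if (max_mismatch == 0) {
    hit <- regexpr(anchor, substr(x, from, lx), fixed = TRUE)[1]
    return(if (hit == -1L) NA_integer_ else from + hit - 1L)
  }
  a <- strsplit(anchor, "", fixed = TRUE)[[1]]
  xs <- strsplit(x, "", fixed = TRUE)[[1]]
  for (i in from:(lx - la + 1L)) {
    if (sum(xs[i:(i + la - 1L)] != a) <= max_mismatch) return(i)
  }
  NA_integer_
}

#' Extract the 9-nt variable region from amplicon reads
#'
#' Locates the left and right anchor sequences in each read (substitutions
#' only, up to `max_mismatch` per anchor; no indels) and returns the enclosed
#' sequence. Reads where either anchor is absent are rejected with reason
#' `"anchor_not_found"`; reads whose enclosed region is not exactly nine bases
#' are rejected with `"bad_length"`.
#'
#' @param reads Character vector of read sequences.
#' @param left_anchor,right_anchor Anchor sequences flanking the variable
#'   region.
#' @param max_anchor_mismatch Maximum substitutions tolerated per anchor.
#' @return Tibble with columns `sequence`, `region` (9-nt string or `NA`) and
#'   `status` (`"ok"`, `"anchor_not_found"` or `"bad_length"`).
#' @export
extract_variable_region <- function(reads, left_anchor, right_anchor,
                                    max_anchor_mismatch = 1) {
  stopifnot(nchar(left_anchor) > 0, nchar(right_anchor) > 0)
  left_anchor <- toupper(left_anchor)
  right_anchor <- toupper(right_anchor)
  one <- function(x) {
    x <- toupper(x)
    i <- find_anchor(x, left_anchor, max_anchor_mismatch)
    if (is.na(i)) return(c(NA_character_, "anchor_not_found"))
    start <- i + nchar(left_anchor)
    j <- find_anchor(x, right_anchor, max_anchor_mismatch, from = start)
    if (is.na(j)) return(c(NA_character_, "anchor_not_found"))
    region <- substr(x, start, j - 1L)
    if (nchar(region) != 9L) return(c(NA_character_, "bad_length"))
    c(region, "ok")
  }
  res <- vapply(reads, one, character(2), USE.NAMES = FALSE)
  tibble::tibble(
    sequence = as.character(reads),
    region = ifelse(res[2, ] == "ok", res[1, ], NA_character_),
    status = res[2, ]
  )
}

#' Count CXXX variants in one replicate's FASTQ file
#'
#' Pipeline per read: anchor-based extraction of the 9-nt variable region,
#' translation through the standard code, rejection of stop-codon and invalid
#' regions, then tallying of the protein variant with the invariant cysteine
#' prepended. Optionally filters reads by mean base quality first. The result
#' is deterministic for a fixed input file.
#'
#' @param fastq_path Path to a FASTQ file (plain or gzip).
#' @param left_anchor,right_anchor Anchors flanking the variable region.
#' @param max_anchor_mismatch Substitutions tolerated per anchor.
#' @param min_mean_quality Optional minimum mean Phred quality per read;
#'   `NULL` (default) disables quality filtering.
#' @param replicate Replicate identifier recorded in the output.
#' @return Tibble with columns `variant`, `replicate`, `count`. Attribute
#'   `"rejections"` is a tibble of `reason`, `n`; attribute `"n_reads"` the
#'   number of records processed. Accepted + rejected = reads processed.
#' @export
count_variants <- function(fastq_path, left_anchor, right_anchor,
                           max_anchor_mismatch = 1, min_mean_quality = NULL,
                           replicate = 1L) {
  if (!file.exists(fastq_path)) {
    rlang::abort(paste0("FASTQ file not found: ", fastq_path))
  }
  qual_scaled <- muffle_metadata_warning(
    Biostrings::readQualityScaledDNAStringSet(fastq_path)
  )
  seqs <- muffle_metadata_warning(as.character(qual_scaled))
  n_reads <- length(seqs)
  rej <- c(low_quality = 0L, anchor_not_found = 0L, bad_length = 0L,
           bad_base = 0L, stop_codon = 0L)

  if (!is.null(min_mean_quality) && n_reads > 0) {
    q <- methods::as(Biostrings::quality(qual_scaled), "IntegerList")
    meanq <- vapply(q, mean, numeric(1))
    drop <- meanq < min_mean_quality
    rej["low_quality"] <- sum(drop)
    seqs <- seqs[!drop]
  }

  ext <- extract_variable_region(seqs, left_anchor, right_anchor,
                                 max_anchor_mismatch)
  for (reason in c("anchor_not_found", "bad_length")) {
    rej[reason] <- rej[reason] + sum(ext$status == reason)
  }
  regions <- ext$region[ext$status == "ok"]
  tr <- translate_variable_region(regions)
  for (reason in c("bad_base", "stop_codon")) {
    rej[reason] <- rej[reason] + sum(tr$status == reason)
  }
  proteins <- paste0("C", tr$protein[tr$status == "ok"])

  counts <- if (length(proteins) > 0) {
    tab <- table(proteins)
    tibble::tibble(variant = names(tab), replicate = as.integer(replicate),
                   count = as.integer(tab))
  } else {
    tibble::tibble(variant = character(), replicate = integer(),
                   count = integer())
  }
  attr(counts, "rejections") <- tibble::tibble(reason = names(rej),
                                               n = as.integer(rej))
  attr(counts, "n_reads") <- n_reads
  counts
}

#' Merge per-replicate count tables into one library-level table
#'
#' Stacks replicate tables for one library, checks replicate ids are unique,
#' and exposes both the per-replicate tallies (long form) and the per-variant
#' total summed over replicates — the quantity the frequency calculation
#' divides.
#'
#' @param tables A list of per-replicate count tibbles (from
#'   [count_variants()] or equivalent, columns `variant`, `replicate`,
#'   `count`), or a single long tibble with those columns.
#' @param library_id Library label stored on the result (e.g. `"naive"`,
#'   `"42C"`).
#' @return Long tibble `variant`, `replicate`, `count` with attributes
#'   `"library_id"` and `"totals"` (tibble `variant`, `total`).
#' @export
merge_replicates <- function(tables, library_id = "library") {
  long <- if (is.data.frame(tables)) tibble::as_tibble(tables) else {
    dplyr::bind_rows(tables)
  }
  if (nrow(long) > 0) {
    stopifnot(all(c("variant", "replicate", "count") %in% names(long)))
    per_rep <- long |> dplyr::count(.data$variant, .data$replicate)
    if (any(per_rep$n > 1)) {
      rlang::abort("duplicate (variant, replicate) entries; replicate ids must be unique")
    }
  }
  totals <- long |>
    dplyr::group_by(.data$variant) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(.data$variant)
  out <- dplyr::arrange(long, .data$variant, .data$replicate)
  attr(out, "library_id") <- library_id
  attr(out, "totals") <- totals
  out
}

#' Spread a merged count table to the wide TSV layout
#'
#' @param merged Output of [merge_replicates()].
#' @return Tibble with columns `variant`, `replicate_1..n`, `total`.
#' @export
counts_to_wide <- function(merged) {
  totals <- attr(merged, "totals")
  if (nrow(merged) == 0) {
    return(tibble::tibble(variant = character(), total = integer()))
  }
  wide <- merged |>
    dplyr::mutate(replicate = paste0("replicate_", .data$replicate)) |>
    tidyr::pivot_wider(names_from = "replicate", values_from = "count",
                       values_fill = 0L)
  dplyr::left_join(wide, totals, by = "variant")
}
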