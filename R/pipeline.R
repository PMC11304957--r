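# End-to-end replay of the screen analysis on synthetic data, with file-based
# stage outputs so real data can be substituted at any stage.

write_tsv_commented <- function(df, path, meta) {
  header <- paste0("# ", names(meta), ": ", unlist(meta))
  con <- file(path, open = "wb")  # binary mode: byte-stable line endings
  on.exit(close(con))
  writeLines(header, con)
  body <- readr::format_tsv(df)
  writeLines(sub("\n$", "", body), con, sep = "\n")
}

#' Read a pipeline TSV, skipping the provenance header
#'
#' @param path Path to a TSV written by [run_screen_pipeline()].
#' @return A tibble.
#' @export
read_pipeline_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' Run the full screen analysis on synthetic data
#'
#' Replays the whole analysis end to end: simulate the thermotolerance screen
#' at the count level, aggregate replicates, compute per-library frequencies
#' and E-Scores (37C and 42C against naive; the 25C library is computed and
#' exported but never used as an E-Score denominator), export scatter tables,
#' select and profile the enriched/de-enriched subsets, compute the
#' library-coverage report, and run the colony-screen comparison. Every
#' output TSV carries a provenance header (tool version, seed); a JSON run
#' manifest records the configuration and per-file checksums. Two runs with
#' the same configuration produce byte-identical artifacts.
#'
#' @param out_dir Output directory (created; existing files overwritten).
#' @param config A [sim_config()].
#' @param top_n Size of the top/bottom subsets profiled at 42C (default 500).
#' @param deenriched_cutoff 37C E-Score cutoff defining the strongly
#'   de-enriched subset (default 0.2).
#' @param rho_n_colonies,rho_gene_conversion,rho_duplicate_fraction
#'   Colony-screen simulation parameters (see [simulate_rho1_colonies()]).
#' @param ruleset A [caax_ruleset()].
#' @return Invisibly, the manifest as a list.
#' @export
run_screen_pipeline <- function(out_dir,
                                config = sim_config(),
                                top_n = 500,
                                deenriched_cutoff = 0.2,
                                rho_n_colonies = 200,
                                rho_gene_conversion = 83 / 200,
                                rho_duplicate_fraction = 5 / 117,
                                ruleset = caax_ruleset()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(tool = "caaxscreen",
               version = as.character(utils::packageVersion("caaxscreen")),
               seed = config$seed)
  emit <- function(df, name) {
    write_tsv_commented(df, file.path(out_dir, name), meta)
  }

  universe <- utils::head(cxxx_variants(), config$library_size)
  counts <- simulate_screen_counts(config, conditions = c("25C", "37C", "42C"),
                                   ruleset = ruleset)

  libs <- unique(counts$library_id)
  freqs <- list()
  for (lib in libs) {
    merged <- merge_replicates(dplyr::filter(counts, .data$library_id == lib),
                               library_id = lib)
    emit(counts_to_wide(merged), paste0("counts_", lib, ".tsv"))
    fr <- compute_frequencies(merged, universe = universe, library_id = lib)
    emit(fr, paste0("frequency_", lib, ".tsv"))
    freqs[[lib]] <- fr
  }

  escores <- list()
  for (cond in c("37C", "42C")) {
    es <- suppressWarnings(compute_escores(freqs[[cond]], freqs[["naive"]]))
    escores[[cond]] <- es
    emit(es, paste0("escore_", cond, ".tsv"))
    emit(export_scatter(freqs[["naive"]], freqs[[cond]]),
         paste0("scatter_", cond, ".tsv"))
  }

  subsets <- list(
    top_42C = select_top_n(escores[["42C"]], top_n, "top"),
    bottom_42C = select_top_n(escores[["42C"]], top_n, "bottom"),
    deenriched_37C = select_by_threshold(escores[["37C"]], deenriched_cutoff,
                                         "<")
  )
  for (nm in names(subsets)) {
    sub <- subsets[[nm]]
    emit(sub, paste0("subset_", nm, ".tsv"))
    if (nrow(sub) > 0) {
      emit(annotate_classes(build_pfm(sub$variant)), paste0("pfm_", nm, ".tsv"))
      emit(composition_stats(sub$variant, ruleset),
           paste0("composition_", nm, ".tsv"))
    }
  }

  emit(tibble::tibble(
    L = config$library_size, n = config$cfu_count,
    mode = c("expected", "complete"),
    coverage = c(expected_coverage(config$library_size, config$cfu_count),
                 prob_complete_coverage(config$library_size, config$cfu_count))
  ), "coverage.tsv")

  colonies <- simulate_rho1_colonies(
    n_colonies = rho_n_colonies,
    gene_conversion_fraction = rho_gene_conversion,
    duplicate_pick_fraction = rho_duplicate_fraction,
    seed = config$seed
  )
  emit(colonies, "rho1_colonies.tsv")
  ded <- dedup_hits(colonies$dna, parent_dna = "GTTTTGTTG")
  emit(glance(ded), "rho1_dedup_report.tsv")
  emit(tidy(ded), "rho1_hit_variants.tsv")
  emit(crossref_escores(tidy(ded)$variant, escores[["42C"]]),
       "rho1_crossref_42C.tsv")
  split <- split_by_consensus(tidy(ded)$variant, ruleset)
  for (nm in names(split)) {
    if (length(split[[nm]]) > 0) {
      emit(annotate_classes(build_pfm(split[[nm]])),
           paste0("pfm_rho1_", nm, ".tsv"))
    }
  }

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    tool = "caaxscreen",
    version = as.character(utils::packageVersion("caaxscreen")),
    config = unclass(config),
    parameters = list(top_n = top_n, deenriched_cutoff = deenriched_cutoff,
                      rho_n_colonies = rho_n_colonies,
                      rho_gene_conversion = rho_gene_conversion,
                      rho_duplicate_fraction = rho_duplicate_fraction),
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files
    ))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
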