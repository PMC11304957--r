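# Synthetic screen generator: Dirichlet-multinomial naive library, exponential
# growth under per-variant fitness, multinomial read sampling with uniform
# substitution error. One global seed; stages consume a stream derived from it.

#' Simulation configuration for the thermotolerance screen
#'
#' Captures every knob of the synthetic screen in one validated list. Defaults
#' mirror the screen design: the complete 8,000-member library, ~150,000
#' colony-forming units per replicate, 10 replicates per condition, and at
#' least 8 rounds of population doubling under selection. The naive pool is
#' sequenced ten-fold deeper than the selected pools because it is the shared
#' denominator of every enrichment score, so denominator noise (and the ratio
#' estimator's finite-count bias) must stay negligible.
#'
#' @param library_size Number of variants in the library (default 8000, the
#'   full C-fixed tetrapeptide space).
#' @param cfu_count Colony-forming units seeding each replicate culture.
#' @param replicates Replicate cultures per condition.
#' @param doublings Rounds of population doubling under selection.
#' @param read_depth_per_replicate Sequencing reads per selected-condition
#'   replicate.
#' @param naive_read_depth_per_replicate Sequencing reads per naive-library
#'   replicate.
#' @param base_error_rate Per-base probability of a uniform substitution error
#'   in simulated reads.
#' @param naive_abundance_dispersion Symmetric Dirichlet concentration for the
#'   library-wide naive abundance vector; smaller values give more uneven
#'   naive frequencies.
#' @param left_anchor,right_anchor Fixed sequences flanking the 9-nt variable
#'   region in simulated amplicon reads.
#' @param seed Integer seed governing every stochastic stage.
#' @return A list with class `sim_config`.
#' @export
sim_config <- function(library_size = 8000,
                       cfu_count = 150000,
                       replicates = 10,
                       doublings = 8,
                       read_depth_per_replicate = 100000,
                       naive_read_depth_per_replicate = 1000000,
                       base_error_rate = 0.001,
                       naive_abundance_dispersion = 5,
                       left_anchor = "GCTGCTAGCGGTACCGATCA",
                       right_anchor = "TGAGCGGCCGCTTCTAGAGC",
                       seed = 1L) {
  cfg <- list(
    library_size = as.integer(library_size),
    cfu_count = as.integer(cfu_count),
    replicates = as.integer(replicates),
    doublings = as.numeric(doublings),
    read_depth_per_replicate = as.integer(read_depth_per_replicate),
    naive_read_depth_per_replicate = as.integer(naive_read_depth_per_replicate),
    base_error_rate = as.numeric(base_error_rate),
    naive_abundance_dispersion = as.numeric(naive_abundance_dispersion),
    left_anchor = toupper(left_anchor),
    right_anchor = toupper(right_anchor),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$library_size >= 1, cfg$cfu_count >= 1, cfg$replicates >= 1,
    cfg$doublings >= 0, cfg$read_depth_per_replicate >= 1,
    cfg$naive_read_depth_per_replicate >= 1,
    cfg$base_error_rate >= 0, cfg$base_error_rate <= 1,
    cfg$naive_abundance_dispersion > 0,
    grepl("^[ACGT]+$", cfg$left_anchor), grepl("^[ACGT]+$", cfg$right_anchor)
  )
  structure(cfg, class = "sim_config")
}

# Evaluate expr under a derived seed, restoring the caller's RNG state.
with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.integer(seed) + 7919L * as.integer(stream)) %% 2147483587L)
  force(expr)
}

#' Default growth-rate table for the fitness model
#'
#' Relative growth rates per motif tier, per reporter and condition, on a
#' 0-1 scale (fraction of the maximal doubling rate). The tiers are derived
#' from the motif classification: `shunted` (consensus X, non-BCA a2, no
#' restrictive residue: prenylated but uncleaved), `canonical` (full
#' Cx[V/I/L][L/F/I/M/V] profile: prenylated and proteolysed), `restrictive`
#' (a2 of D/E/K/R or X of K/R/P: prenylation blocked) and `nonconsensus`
#' (everything else: largely unmodified). Magnitudes are the package's own
#' calibration of the screen's qualitative outcome — shunted variants dominate
#' under selection, canonically processed ones underperform even unmodified
#' protein, restrictive ones grow worst at 42C — not measured rates. The 37C
#' table has a smaller spread and puts canonical variants lowest, matching the
#' milder selection where only the canonically processed cluster is strongly
#' de-enriched. The Rho1 reporter is a viability rule: any prenylated variant
#' (shunted or canonical) survives counterselection, others do not.
#'
#' @return Nested list: `rates[[reporter]][[condition]]` is a named numeric
#'   vector over the four tiers.
#' @export
default_fitness_rates <- function() {
  list(
    ydj1 = list(
      "25C" = c(shunted = 1, canonical = 1, nonconsensus = 1, restrictive = 1),
      "37C" = c(shunted = 1, canonical = 0.30, nonconsensus = 0.85,
                restrictive = 0.70),
      "42C" = c(shunted = 1, canonical = 0.35, nonconsensus = 0.25,
                restrictive = 0.10)
    ),
    rho1 = list(
      viability = c(shunted = 1, canonical = 1, nonconsensus = 0,
                    restrictive = 0)
    )
  )
}

#' Assign ground-truth fitness to every library variant
#'
#' Classifies each variant (see [classify_motifs()]), maps it to one of the
#' four motif tiers (restrictive takes precedence over the consensus flags so
#' an overridden ruleset cannot leave a variant in two tiers), and looks up the
#' tier's growth rate for the requested reporter and condition.
#'
#' @param variants Data frame with a `variant` column, or `NULL` for the full
#'   enumeration.
#' @param reporter `"ydj1"` or `"rho1"`.
#' @param condition Condition name present in the rate table (for Ydj1:
#'   `"25C"`, `"37C"`, `"42C"`; for Rho1: `"viability"`).
#' @param rates Rate table, see [default_fitness_rates()].
#' @param ruleset Motif ruleset, see [caax_ruleset()].
#' @return Tibble with columns `variant`, `tier`, `fitness` and `viable`
#'   (`fitness > 0`).
#' @examples
#' ft <- assign_fitness(condition = "42C")
#' dplyr::count(ft, tier)
#' @export
assign_fitness <- function(variants = NULL, reporter = c("ydj1", "rho1"),
                           condition = "42C",
                           rates = default_fitness_rates(),
                           ruleset = caax_ruleset()) {
  reporter <- match.arg(reporter)
  if (is.null(variants)) variants <- cxxx_variants()
  tbl <- rates[[reporter]]
  if (is.null(tbl) || is.null(tbl[[condition]])) {
    rlang::abort(paste0("no rate table for reporter '", reporter,
                        "', condition '", condition, "'"))
  }
  rt <- tbl[[condition]]
  needed <- c("shunted", "canonical", "nonconsensus", "restrictive")
  if (!all(needed %in% names(rt))) {
    rlang::abort("rate table must name all four motif tiers")
  }
  cls <- classify_motifs(variants, ruleset = ruleset)
  tier <- dplyr::case_when(
    cls$restrictive ~ "restrictive",
    cls$canonical_cleavable ~ "canonical",
    cls$x_consensus & !cls$a2_bca ~ "shunted",
    TRUE ~ "nonconsensus"
  )
  tibble::tibble(
    variant = cls$variant,
    tier = tier,
    fitness = unname(rt[tier]),
    viable = unname(rt[tier]) > 0
  )
}

#' Draw the naive library: abundance vector plus per-replicate colony counts
#'
#' The library-wide abundance vector is a single draw from a symmetric
#' Dirichlet (one pool of transformants feeds every replicate); each
#' replicate's colony counts are then an independent multinomial of
#' `cfu_count` colonies from that vector. This reproduces the uneven naive
#' frequencies seen in real transformation pools without modelling their
#' cause.
#'
#' @param config A [sim_config()].
#' @param variants Optional data frame with a `variant` column; defaults to
#'   the first `library_size` variants of the full enumeration.
#' @return Long tibble with columns `variant`, `replicate`, `count`; the
#'   shared abundance vector is attached as attribute `"abundance"` (a tibble
#'   of `variant`, `p`).
#' @export
build_naive_library <- function(config = sim_config(), variants = NULL) {
  if (is.null(variants)) {
    variants <- utils::head(cxxx_variants(), config$library_size)
  }
  if (nrow(variants) != config$library_size) {
    rlang::abort("library_size does not match the supplied variant set")
  }
  v <- variants$variant
  with_stream(config$seed, 1L, {
    g <- stats::rgamma(length(v), shape = config$naive_abundance_dispersion)
    p <- g / sum(g)
    counts <- stats::rmultinom(config$replicates, config$cfu_count, p)
  })
  out <- tibble::tibble(
    variant = rep(v, times = config$replicates),
    replicate = rep(seq_len(config$replicates), each = length(v)),
    count = as.integer(counts)
  )
  attr(out, "abundance") <- tibble::tibble(variant = v, p = p)
  out
}

#' Grow a population deterministically under per-variant fitness
#'
#' Applies the exponential growth law N' = N * 2^(f * D): a variant at the
#' maximal rate (f = 1) doubles once per round, slower variants double
#' fractionally. Renormalisation is deferred to read sampling.
#'
#' @param abundances Nonnegative numeric vector of population sizes.
#' @param fitness Numeric vector in `[0, 1]`, recycled against `abundances`.
#' @param doublings Number of doubling rounds (nonnegative).
#' @return Numeric vector of grown population sizes.
#' @examples
#' grow_population(1, 1, 8)              # 256
#' grow_population(c(1, 1), c(1, 0.5), 8) # ratio 16
#' @export
grow_population <- function(abundances, fitness, doublings) {
  if (any(abundances < 0)) rlang::abort("abundances must be nonnegative")
  if (any(fitness < 0 | fitness > 1)) {
    rlang::abort("fitness values must lie in [0, 1]")
  }
  if (doublings < 0) rlang::abort("doublings must be nonnegative")
  abundances * 2^(fitness * doublings)
}

#' Simulate per-replicate variant counts for a full screen
#'
#' Runs the whole counting-level screen in one call: naive pool, growth of
#' each replicate under the condition's fitness model, and multinomial read
#' sampling at the configured depth. Sequencing error is not applied at the
#' count level (reads that acquire errors inside the 9-nt variable region are
#' a property of the FASTQ path; see [sequence_reads()]).
#'
#' @param config A [sim_config()].
#' @param conditions Character vector of selected conditions to simulate
#'   (subset of the Ydj1 rate table's names).
#' @param rates,ruleset Passed to [assign_fitness()].
#' @return Long tibble with columns `library_id` (`"naive"` plus each
#'   condition), `replicate`, `variant`, `count`. The naive abundance vector
#'   and the per-condition fitness tables are attached as attributes
#'   `"abundance"` and `"fitness"`.
#' @export
simulate_screen_counts <- function(config = sim_config(),
                                   conditions = c("25C", "37C", "42C"),
                                   rates = default_fitness_rates(),
                                   ruleset = caax_ruleset()) {
  variants <- utils::head(cxxx_variants(), config$library_size)
  naive <- build_naive_library(config, variants)
  p <- attr(naive, "abundance")$p
  v <- variants$variant

  naive_reads <- with_stream(config$seed, 2L, {
    stats::rmultinom(config$replicates, config$naive_read_depth_per_replicate, p)
  })
  pieces <- list(tibble::tibble(
    library_id = "naive",
    replicate = rep(seq_len(config$replicates), each = length(v)),
    variant = rep(v, times = config$replicates),
    count = as.integer(naive_reads)
  ))

  fits <- list()
  for (k in seq_along(conditions)) {
    cond <- conditions[[k]]
    ft <- assign_fitness(variants, reporter = "ydj1", condition = cond,
                         rates = rates, ruleset = ruleset)
    fits[[cond]] <- ft
    counts <- with_stream(config$seed, 10L + k, {
      sapply(seq_len(config$replicates), function(r) {
        n0 <- naive$count[naive$replicate == r]
        grown <- grow_population(n0, ft$fitness, config$doublings)
        if (sum(grown) <= 0) rlang::abort("population collapsed to zero")
        stats::rmultinom(1, config$read_depth_per_replicate, grown / sum(grown))
      })
    })
    pieces[[k + 1L]] <- tibble::tibble(
      library_id = cond,
      replicate = rep(seq_len(config$replicates), each = length(v)),
      variant = rep(v, times = config$replicates),
      count = as.integer(counts)
    )
  }
  out <- dplyr::bind_rows(pieces)
  attr(out, "abundance") <- attr(naive, "abundance")
  attr(out, "fitness") <- fits
  out
}

# codons (as 3-mers) per amino acid, standard code, stops removed
codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc <- gc[gc != "*"]
  split(names(gc), unname(gc))
}

# Deterministic coding 9-mer for a variant's three variable residues: the
# lexicographically first codon of each amino acid.
canonical_coding_dna <- function(variants) {
  tab <- vapply(codons_by_aa(), function(x) sort(x)[1], character(1))
  vapply(variants, function(v) {
    paste0(tab[[substr(v, 2, 2)]], tab[[substr(v, 3, 3)]], tab[[substr(v, 4, 4)]])
  }, character(1), USE.NAMES = FALSE)
}

# Random synonymous coding 9-mer per variant (consumes RNG).
random_coding_dna <- function(variants) {
  tab <- codons_by_aa()
  vapply(variants, function(v) {
    paste0(
      sample(tab[[substr(v, 2, 2)]], 1),
      sample(tab[[substr(v, 3, 3)]], 1),
      sample(tab[[substr(v, 4, 4)]], 1)
    )
  }, character(1), USE.NAMES = FALSE)
}

apply_base_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0) return(reads)
  bases <- c("A", "C", "G", "T")
  m <- do.call(rbind, strsplit(reads, "", fixed = TRUE))
  hit <- which(stats::runif(length(m)) < error_rate)
  if (length(hit) > 0) {
    # replace with a uniformly chosen *different* base
    repl <- vapply(m[hit], function(b) sample(setdiff(bases, b), 1),
                   character(1), USE.NAMES = FALSE)
    m[hit] <- repl
  }
  apply(m, 1, paste0, collapse = "")
}

#' Simulate amplicon reads for one replicate
#'
#' Draws `depth` reads multinomially in proportion to the supplied abundances
#' and emits each as `left_anchor + coding 9-mer + right_anchor`, with every
#' base independently substituted at `base_error_rate`. Each variant is
#' encoded by a fixed (lexicographically first) codon choice; codon usage does
#' not affect downstream protein-level counting.
#'
#' @param abundances Tibble with columns `variant` and a nonnegative weight
#'   column `abundance`.
#' @param config A [sim_config()] (anchors, error rate).
#' @param depth Number of reads to draw.
#' @param stream Integer stream id mixed into the seed so different replicates
#'   get independent draws.
#' @return Tibble with columns `read_id`, `sequence`, `true_variant`.
#' @export
sequence_reads <- function(abundances, config = sim_config(),
                           depth = config$read_depth_per_replicate,
                           stream = 100L) {
  stopifnot(is.data.frame(abundances),
            all(c("variant", "abundance") %in% names(abundances)))
  if (nrow(abundances) == 0) rlang::abort("empty abundance vector")
  if (depth <= 0) rlang::abort("depth must be positive")
  w <- abundances$abundance
  if (any(w < 0) || sum(w) <= 0) rlang::abort("abundances must be nonnegative with positive sum")
  dna <- canonical_coding_dna(abundances$variant)
  with_stream(config$seed, stream, {
    idx <- sample.int(nrow(abundances), size = depth, replace = TRUE,
                      prob = w / sum(w))
    seqs <- paste0(config$left_anchor, dna[idx], config$right_anchor)
    seqs <- apply_base_errors(seqs, config$base_error_rate)
  })
  tibble::tibble(
    read_id = sprintf("read_%06d", seq_len(depth)),
    sequence = seqs,
    true_variant = abundances$variant[idx]
  )
}

#' Write a full simulated screen to FASTQ files
#'
#' Materialises [simulate_screen_counts()] output as 4-line FASTQ, one file
#' per library/replicate (`<library>_rep<k>.fastq`), with constant quality
#' "I" (Q40). Per-base substitution errors are applied to each read. Also
#' writes the ground-truth fitness tables (`fitness_<condition>.tsv`).
#'
#' @param dir Output directory (created if needed).
#' @param config A [sim_config()].
#' @param conditions Selected conditions to simulate.
#' @param depth Reads per replicate per library (kept small for FASTQ runs;
#'   defaults to `config$read_depth_per_replicate`).
#' @inheritParams simulate_screen_counts
#' @return Invisibly, a tibble manifest of written files with columns
#'   `library_id`, `replicate`, `path`.
#' @export
simulate_screen_fastq <- function(dir, config = sim_config(),
                                  conditions = c("37C", "42C"),
                                  depth = config$read_depth_per_replicate,
                                  rates = default_fitness_rates(),
                                  ruleset = caax_ruleset()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  variants <- utils::head(cxxx_variants(), config$library_size)
  naive <- build_naive_library(config, variants)
  manifest <- list()
  libs <- c("naive", conditions)
  for (li in seq_along(libs)) {
    lib <- libs[[li]]
    fit <- if (lib == "naive") {
      rep(1, nrow(variants))
    } else {
      assign_fitness(variants, "ydj1", lib, rates, ruleset)$fitness
    }
    dbl <- if (lib == "naive") 0 else config$doublings
    for (r in seq_len(config$replicates)) {
      n0 <- naive$count[naive$replicate == r]
      grown <- grow_population(n0, fit, dbl)
      reads <- sequence_reads(
        tibble::tibble(variant = variants$variant, abundance = grown),
        config = config, depth = depth, stream = 1000L + 100L * li + r
      )
      path <- file.path(dir, sprintf("%s_rep%02d.fastq", lib, r))
      seqs <- Biostrings::DNAStringSet(reads$sequence)
      names(seqs) <- reads$read_id
      quals <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
      Biostrings::writeXStringSet(seqs, path, format = "fastq",
                                  qualities = quals)
      manifest[[length(manifest) + 1L]] <-
        tibble::tibble(library_id = lib, replicate = r, path = path)
    }
  }
  for (cond in conditions) {
    ft <- assign_fitness(variants, "ydj1", cond, rates, ruleset)
    readr::write_tsv(ft, file.path(dir, paste0("fitness_", cond, ".tsv")))
  }
  invisible(dplyr::bind_rows(manifest))
}

#' Simulate the colony-based viability screen
#'
#' Emulates picking `n_colonies` plasmids from a survivor plate of the
#' orthogonal viability screen: a `gene_conversion_fraction` of picks carry
#' the exact parent (wild-type) coding sequence because of recombination with
#' the resident plasmid; among the remaining picks, a `duplicate_pick_fraction`
#' re-sample an earlier non-parent pick (double-picked colonies); the rest are
#' fresh survivors — a viable variant drawn uniformly, encoded with random
#' synonymous codons so distinct DNA can encode the same protein.
#'
#' @param n_colonies Number of colonies picked.
#' @param gene_conversion_fraction Probability a pick is the exact parent DNA.
#' @param duplicate_pick_fraction Probability a non-parent pick duplicates an
#'   earlier non-parent pick.
#' @param parent_dna 9-nt coding sequence of the parent (wild-type CVLL by
#'   default).
#' @param fitness Rho1-mode fitness table (see [assign_fitness()]); only
#'   `viable` is used.
#' @param seed Integer seed.
#' @return Tibble with columns `colony`, `dna` (9-nt variable region) and
#'   `origin` (`"parent"`, `"duplicate"` or `"new"`).
#' @export
simulate_rho1_colonies <- function(n_colonies = 200,
                                   gene_conversion_fraction = 83 / 200,
                                   duplicate_pick_fraction = 5 / 117,
                                   parent_dna = "GTTTTGTTG",
                                   fitness = assign_fitness(reporter = "rho1",
                                                            condition = "viability"),
                                   seed = 1L) {
  viable <- fitness$variant[fitness$viable]
  if (length(viable) == 0) rlang::abort("no viable variants under this model")
  dna <- character(n_colonies)
  origin <- character(n_colonies)
  with_stream(seed, 3L, {
    for (i in seq_len(n_colonies)) {
      if (stats::runif(1) < gene_conversion_fraction) {
        dna[i] <- parent_dna
        origin[i] <- "parent"
      } else {
        prior <- which(origin[seq_len(i - 1L)] %in% c("duplicate", "new"))
        if (length(prior) > 0 && stats::runif(1) < duplicate_pick_fraction) {
          dna[i] <- dna[sample(prior, 1)]
          origin[i] <- "duplicate"
        } else {
          v <- viable[sample.int(length(viable), 1)]
          dna[i] <- random_coding_dna(v)
          origin[i] <- "new"
        }
      }
    }
  })
  tibble::tibble(colony = seq_len(n_colonies), dna = dna, origin = origin)
}
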