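test_that("naive library draws conserve colony counts and respect the seed", {
  cfg <- sim_config(library_size = 50, cfu_count = 1000, replicates = 3,
                    seed = 5)
  lib1 <- build_naive_library(cfg)
  lib2 <- build_naive_library(cfg)
  expect_identical(lib1, lib2)
  per_rep <- tapply(lib1$count, lib1$replicate, sum)
  expect_true(all(per_rep == 1000))
  ab <- attr(lib1, "abundance")
  expect_equal(sum(ab$p), 1, tolerance = 1e-12)
  expect_true(all(ab$p > 0))
  # a different seed gives different draws
  lib3 <- build_naive_library(sim_config(library_size = 50, cfu_count = 1000,
                                         replicates = 3, seed = 6))
  expect_false(identical(lib1$count, lib3$count))
})

test_that("near-uniform dispersion gives near-even expected naive counts", {
  cfg <- sim_config(library_size = 2, cfu_count = 10000, replicates = 1,
                    naive_abundance_dispersion = 1e7, seed = 2)
  lib <- build_naive_library(cfg)
  expect_equal(sum(lib$count), 10000)
  expect_equal(lib$count[1] / 10000, 0.5, tolerance = 0.05)
})

test_that("population growth follows N * 2^(f*D)", {
  expect_equal(grow_population(1, 1, 8), 256)
  expect_equal(grow_population(1, 0, 8), 1)
  grown <- grow_population(c(1, 1), c(1, 0.5), 8)
  expect_equal(grown[1] / grown[2], 16)
  expect_error(grow_population(-1, 1, 8), "nonnegative")
  expect_error(grow_population(1, 2, 8), "\\[0, 1\\]")
})

test_that("fitness assignment covers every variant and ranks tiers as designed", {
  ft <- assign_fitness(condition = "42C")
  expect_equal(nrow(ft), 8000L)
  expect_false(any(is.na(ft$fitness)))
  by_tier <- tapply(ft$fitness, ft$tier, unique)
  expect_true(by_tier[["shunted"]] > by_tier[["canonical"]])
  expect_true(by_tier[["canonical"]] > by_tier[["restrictive"]])
  expect_equal(ft$tier[ft$variant == "CSFL"], "shunted")
  expect_equal(unname(ft$fitness[ft$variant == "CSFL"]), max(ft$fitness))
  expect_true(ft$fitness[ft$variant == "CVLL"] < ft$fitness[ft$variant == "CSFL"])
  # Rho1 mode: prenylatable variants viable, others not
  rho <- assign_fitness(reporter = "rho1", condition = "viability")
  expect_true(rho$viable[rho$variant == "CVLL"])
  expect_true(rho$viable[rho$variant == "CSFL"])
  expect_false(rho$viable[rho$variant == "CASQ"])
  expect_error(assign_fitness(condition = "99C"), "no rate table")
})

test_that("read simulation conserves depth, respects the seed, and encodes the variant", {
  cfg <- sim_config(library_size = 4, base_error_rate = 0, seed = 3)
  ab <- tibble::tibble(variant = "CVLL", abundance = 1)
  reads <- sequence_reads(ab, cfg, depth = 3)
  expect_equal(nrow(reads), 3L)
  expect_true(all(grepl("GT[ACGT]CT[ACGT]CT[ACGT]",
                        substr(reads$sequence, 21, 29))))
  # region translates back to VLL
  region <- substr(reads$sequence, nchar(cfg$left_anchor) + 1,
                   nchar(cfg$left_anchor) + 9)
  expect_true(all(translate_variable_region(region)$protein == "VLL"))
  expect_identical(sequence_reads(ab, cfg, depth = 3),
                   sequence_reads(ab, cfg, depth = 3))
  expect_error(sequence_reads(ab[0, ], cfg, depth = 3), "empty")
})

test_that("base errors hit roughly the configured fraction of bases", {
  cfg <- sim_config(base_error_rate = 0.1, seed = 9)
  ab <- tibble::tibble(variant = "CVLL", abundance = 1)
  reads <- sequence_reads(ab, cfg, depth = 200)
  template <- sequence_reads(ab, sim_config(base_error_rate = 0, seed = 9),
                             depth = 1)$sequence[1]
  mism <- mapply(function(s) {
    sum(strsplit(s, "")[[1]] != strsplit(template, "")[[1]])
  }, reads$sequence)
  rate <- sum(mism) / (200 * nchar(template))
  expect_gt(rate, 0.05)
  expect_lt(rate, 0.15)
})

test_that("simulated screen counts conserve read depth per replicate", {
  cfg <- sim_config(library_size = 100, cfu_count = 5000, replicates = 4,
                    read_depth_per_replicate = 2000,
                    naive_read_depth_per_replicate = 8000, seed = 4)
  cnt <- simulate_screen_counts(cfg, conditions = "42C")
  sel <- cnt[cnt$library_id == "42C", ]
  nai <- cnt[cnt$library_id == "naive", ]
  expect_true(all(tapply(sel$count, sel$replicate, sum) == 2000))
  expect_true(all(tapply(nai$count, nai$replicate, sum) == 8000))
  expect_identical(cnt, simulate_screen_counts(cfg, conditions = "42C"))
})

test_that("colony-screen simulation hits the calibrated expectations and edge cases", {
  picks <- simulate_rho1_colonies(seed = 21)
  expect_equal(nrow(picks), 200L)
  expect_true(all(picks$origin %in% c("parent", "duplicate", "new")))
  expect_true(all(picks$dna[picks$origin == "parent"] == "GTTTTGTTG"))
  # every simulated pick encodes a viable variant
  tr <- translate_variable_region(picks$dna)
  expect_true(all(tr$status == "ok"))
  viable <- assign_fitness(reporter = "rho1", condition = "viability")
  expect_true(all(paste0("C", tr$protein) %in%
                    viable$variant[viable$viable]))
  # degenerate settings
  all_parent <- simulate_rho1_colonies(gene_conversion_fraction = 1, seed = 1)
  expect_true(all(all_parent$dna == "GTTTTGTTG"))
  no_dup <- simulate_rho1_colonies(n_colonies = 50,
                                   gene_conversion_fraction = 0,
                                   duplicate_pick_fraction = 0, seed = 2)
  expect_true(all(no_dup$origin == "new"))
})

test_that("FASTQ emission is byte-identical under a fixed seed", {
  cfg <- sim_config(library_size = 10, cfu_count = 200, replicates = 2,
                    read_depth_per_replicate = 50, seed = 8)
  d1 <- file.path(tempdir(), "fq1"); d2 <- file.path(tempdir(), "fq2")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- simulate_screen_fastq(d1, cfg, conditions = "42C", depth = 50)
  m2 <- simulate_screen_fastq(d2, cfg, conditions = "42C", depth = 50)
  expect_equal(nrow(m1), 2 * 2)  # (naive + 42C) x 2 replicates
  for (i in seq_len(nrow(m1))) {
    expect_identical(readLines(m1$path[i]), readLines(m2$path[i]))
  }
  # 4-line FASTQ with the configured depth
  expect_equal(length(readLines(m1$path[1])), 4 * 50)
})
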