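anchor_l <- "GCTGCTAGCGGTACCGATCA"
anchor_r <- "TGAGCGGCCGCTTCTAGAGC"

test_that("variable-region extraction finds anchors and rejects malformed reads", {
  ok <- paste0(anchor_l, "GTTTTGTTG", anchor_r)
  short <- paste0(anchor_l, "GTTTTG", anchor_r)
  none <- "ACGTACGTACGTACGTACGTACGTACGT"
  res <- extract_variable_region(c(ok, short, none), anchor_l, anchor_r)
  expect_equal(res$region[1], "GTTTTGTTG")
  expect_equal(res$status, c("ok", "bad_length", "anchor_not_found"))
  # one substitution inside an anchor is tolerated at the default setting
  mut <- ok
  substr(mut, 3, 3) <- "A"
  expect_equal(extract_variable_region(mut, anchor_l, anchor_r)$status, "ok")
  # two substitutions in the same anchor are not
  substr(mut, 5, 5) <- "A"
  expect_equal(extract_variable_region(mut, anchor_l, anchor_r)$status,
               "anchor_not_found")
})

test_that("counting a small FASTQ matches brute-force string counting", {
  enc <- c(CVLL = "GTTTTGTTG", CSFL = "TCTTTTTTG")
  seqs <- paste0(anchor_l, enc[c("CVLL", "CVLL", "CSFL")], anchor_r)
  fq <- small_fastq(tempfile(fileext = ".fastq"), seqs)
  counts <- count_variants(fq, anchor_l, anchor_r)
  expect_equal(counts$count[counts$variant == "CVLL"], 2L)
  expect_equal(counts$count[counts$variant == "CSFL"], 1L)
  rej <- attr(counts, "rejections")
  expect_equal(sum(rej$n), 0L)
  expect_equal(attr(counts, "n_reads"), 3L)
})

test_that("stop-codon and malformed reads are tallied under rejections, not variants", {
  seqs <- c(
    paste0(anchor_l, "GTTTTGTTG", anchor_r),   # ok
    paste0(anchor_l, "TAATTGTTG", anchor_r),   # stop codon
    paste0(anchor_l, "GTTTTG", anchor_r),      # bad length
    "TTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTT"   # no anchors
  )
  fq <- small_fastq(tempfile(fileext = ".fastq"), seqs)
  counts <- count_variants(fq, anchor_l, anchor_r)
  rej <- attr(counts, "rejections")
  expect_equal(sum(counts$count), 1L)
  expect_equal(rej$n[rej$reason == "stop_codon"], 1L)
  expect_equal(rej$n[rej$reason == "bad_length"], 1L)
  expect_equal(rej$n[rej$reason == "anchor_not_found"], 1L)
  # accepted + rejected = records processed
  expect_equal(sum(counts$count) + sum(rej$n), attr(counts, "n_reads"))
})

test_that("error-free simulated FASTQ round-trips to the simulator's exact draws", {
  cfg <- sim_config(library_size = 30, cfu_count = 500, replicates = 2,
                    read_depth_per_replicate = 300, base_error_rate = 0,
                    seed = 12)
  dir <- file.path(tempdir(), "roundtrip")
  unlink(dir, recursive = TRUE)
  manifest <- simulate_screen_fastq(dir, cfg, conditions = "42C", depth = 300)
  for (i in seq_len(nrow(manifest))) {
    counts <- count_variants(manifest$path[i], cfg$left_anchor,
                             cfg$right_anchor,
                             replicate = manifest$replicate[i])
    expect_equal(sum(counts$count), 300L)
    expect_equal(sum(attr(counts, "rejections")$n), 0L)
    # independent oracle: slice the region by position, translate, tally
    reads <- readLines(manifest$path[i])
    seqs <- reads[seq(2, length(reads), by = 4)]
    region <- substr(seqs, nchar(cfg$left_anchor) + 1,
                     nchar(cfg$left_anchor) + 9)
    tr <- translate_variable_region(region)
    oracle <- c(table(paste0("C", tr$protein)))
    got <- setNames(counts$count, counts$variant)
    expect_setequal(names(got), names(oracle))
    nm <- sort(names(got))
    expect_equal(as.integer(got[nm]), as.integer(oracle[nm]))
  }
})

test_that("replicate merging sums totals and rejects duplicate replicate ids", {
  t1 <- tibble::tibble(variant = "CAAA", replicate = 1L, count = 1L)
  t2 <- tibble::tibble(variant = "CAAA", replicate = 2L, count = 2L)
  merged <- merge_replicates(list(t1, t2), library_id = "toy")
  totals <- attr(merged, "totals")
  expect_equal(totals$total[totals$variant == "CAAA"], 3L)
  expect_error(merge_replicates(list(t1, t1)), "unique")
  # empty replicates merge without error
  empty <- tibble::tibble(variant = character(), replicate = integer(),
                          count = integer())
  merged0 <- merge_replicates(list(empty, empty))
  expect_equal(nrow(attr(merged0, "totals")), 0L)
})

test_that("merged totals equal a brute-force recount over replicate tables", {
  set.seed(31)
  tabs <- lapply(1:5, function(r) {
    tibble::tibble(variant = sample(c("CAAA", "CAAC", "CAAD"), 3),
                   replicate = r, count = sample.int(20, 3))
  })
  merged <- merge_replicates(tabs, library_id = "x")
  totals <- attr(merged, "totals")
  all_rows <- do.call(rbind, tabs)
  for (v in unique(all_rows$variant)) {
    expect_equal(totals$total[totals$variant == v],
                 sum(all_rows$count[all_rows$variant == v]))
  }
})

test_that("wide export carries one column per replicate plus the total", {
  t1 <- tibble::tibble(variant = c("CAAA", "CAAC"), replicate = 1L,
                       count = c(1L, 4L))
  t2 <- tibble::tibble(variant = "CAAA", replicate = 2L, count = 2L)
  wide <- counts_to_wide(merge_replicates(list(t1, t2)))
  expect_named(wide, c("variant", "replicate_1", "replicate_2", "total"))
  expect_equal(wide$total[wide$variant == "CAAA"], 3L)
  expect_equal(wide$replicate_2[wide$variant == "CAAC"], 0L)
})
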