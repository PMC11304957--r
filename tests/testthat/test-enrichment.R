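toy_freq <- function(counts, library_id = "lib") {
  compute_frequencies(tibble::tibble(variant = names(counts),
                                     count = as.integer(counts)),
                      library_id = library_id)
}

test_that("frequencies divide totals by the validated grand total", {
  fr <- toy_freq(c(CAAA = 4, CAAC = 6))
  expect_equal(fr$frequency, c(0.4, 0.6))
  expect_equal(toy_freq(c(CVLL = 7))$frequency, 1)
  expect_error(toy_freq(c(CAAA = 0)), "all counts are zero")
  # unobserved universe members get frequency zero
  fr2 <- compute_frequencies(tibble::tibble(variant = "CAAA", count = 5L),
                             universe = tibble::tibble(variant = c("CAAA", "CAAC")))
  expect_equal(fr2$frequency[fr2$variant == "CAAC"], 0)
})

test_that("frequencies over the full library match a brute-force recount", {
  cfg <- sim_config(library_size = 8000, cfu_count = 20000, replicates = 3,
                    read_depth_per_replicate = 5000,
                    naive_read_depth_per_replicate = 5000, seed = 17)
  cnt <- simulate_screen_counts(cfg, conditions = "42C")
  nai <- cnt[cnt$library_id == "naive", ]
  fr <- compute_frequencies(nai, universe = cxxx_variants())
  expect_equal(sum(fr$frequency), 1, tolerance = 1e-9)
  recount <- tapply(nai$count, nai$variant, sum)
  recount <- recount / sum(recount)
  expect_equal(fr$frequency, as.numeric(recount[fr$variant]),
               tolerance = 1e-12)
})

test_that("E-Score identities: self-ratio one, zero numerator zero, scale invariance", {
  fr <- toy_freq(c(CAAA = 3, CAAC = 5, CAAD = 2), "a")
  self <- suppressWarnings(compute_escores(fr, fr))
  expect_true(all(self$escore == 1))
  expect_true(all(self$status == "neutral"))

  sel <- toy_freq(c(CAAA = 0, CAAC = 5, CAAD = 5), "sel")
  es <- compute_escores(sel, fr)
  expect_equal(es$escore[es$variant == "CAAA"], 0)
  expect_equal(es$status[es$variant == "CAAA"], "de-enriched")

  scaled <- toy_freq(c(CAAA = 30, CAAC = 50, CAAD = 20), "a10")
  es1 <- compute_escores(sel, fr)
  es2 <- compute_escores(sel, scaled)
  expect_equal(es1$escore, es2$escore, tolerance = 1e-12)

  half <- compute_escores(toy_freq(c(CAAA = 2, CAAC = 8)),
                          toy_freq(c(CAAA = 4, CAAC = 6)))
  expect_equal(half$escore[half$variant == "CAAA"], 0.5)
})

test_that("undefined scores are flagged, warned about, and excluded from rankings", {
  naive <- toy_freq(c(CAAA = 0, CAAC = 10), "naive")
  sel <- toy_freq(c(CAAA = 5, CAAC = 5), "sel")
  expect_warning(es <- compute_escores(sel, naive), "undefined")
  expect_equal(es$status[es$variant == "CAAA"], "undefined")
  expect_true(is.na(es$escore[es$variant == "CAAA"]))
  expect_equal(select_top_n(es, 1, "top")$variant, "CAAC")
  expect_error(compute_escores(sel, toy_freq(c(CXXX = 1))), "universe")
})

test_that("threshold and top-n selection are deterministic with lexicographic ties", {
  es <- tibble::tibble(
    variant = c("CAAD", "CAAA", "CAAC", "CAAB"),
    escore = c(0.1, 0.3, 2, 2),
    status = "x"
  )
  expect_equal(select_by_threshold(es, 0.2, "<")$variant, "CAAD")
  expect_equal(nrow(select_by_threshold(es, 0.05, "<")), 0L)
  top2 <- select_top_n(es, 2, "top")
  expect_equal(top2$variant, c("CAAB", "CAAC"))  # tie broken alphabetically
  expect_equal(select_top_n(es, 4, "top")$variant,
               c("CAAB", "CAAC", "CAAA", "CAAD"))
  expect_error(select_top_n(es, 0), "positive")
  expect_error(select_top_n(es, 5), "exceeds")
})

test_that("rankings agree with a brute-force double loop on random 50-variant tables", {
  set.seed(99)
  universe <- head(cxxx_variants()$variant, 50)
  for (rep in 1:5) {
    nai <- setNames(sample.int(100, 50, replace = TRUE), universe)
    sel <- setNames(sample.int(100, 50, replace = TRUE), universe)
    es <- compute_escores(toy_freq(sel, "s"), toy_freq(nai, "n"))
    for (n_top in c(1, 10, 50)) {
      expect_equal(select_top_n(es, n_top, "top")$variant,
                   oracle_escore_ranking(sel, nai, n_top))
    }
  }
})

test_that("scatter export pairs frequencies for every universe variant", {
  naive <- toy_freq(c(CAAA = 4, CAAC = 6), "naive")
  sel <- toy_freq(c(CAAA = 1, CAAC = 9), "42C")
  sc <- export_scatter(naive, sel)
  expect_equal(nrow(sc), 2L)
  expect_equal(sc$freq_naive, c(0.4, 0.6))
  expect_equal(sc$freq_selected, c(0.1, 0.9))
  # identical libraries sit on the diagonal
  diag <- export_scatter(naive, naive)
  expect_equal(diag$freq_naive, diag$freq_selected)
  p <- plot_frequency_scatter(sc)
  expect_s3_class(p, "ggplot")
})

test_that("published-layout frequency tables are summarised by recomputed E-Scores", {
  # synthetic three-variant table in the supplementary file's layout
  tab <- tibble::tibble(
    variant = c("CAAA", "CAAC", "CAAD"),
    freq_naive = c(0.5, 0.3, 0.2),
    freq_37C = c(0.05, 0.65, 0.3),
    freq_42C = c(0.02, 0.9, 0.08)
  )
  s <- summarise_published_escores(tab)
  expect_equal(s$max_escore_37C, 0.65 / 0.3)
  expect_equal(s$max_escore_42C, 0.9 / 0.3)
  expect_equal(s$n_deenriched_37C, 1L)  # CAAA at 0.1
})
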