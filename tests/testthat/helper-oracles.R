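# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# all C-prefixed tetrapeptides by explicit triple loop
oracle_enumerate_cxxx <- function() {
  out <- character(0)
  for (a in AMINO_ACIDS) {
    for (b in AMINO_ACIDS) {
      for (x in AMINO_ACIDS) {
        out <- c(out, paste0("C", a, b, x))
      }
    }
  }
  out
}

# rule check written independently of classify_motifs()
oracle_classify <- function(v) {
  a2 <- substr(v, 3, 3)
  x <- substr(v, 4, 4)
  xc <- x %in% c("L", "F", "I", "M", "V")
  bca <- a2 %in% c("V", "I", "L")
  list(
    x_consensus = xc, a2_bca = bca, canonical_cleavable = xc & bca,
    restrictive = a2 %in% c("D", "E", "K", "R") | x %in% c("K", "R", "P")
  )
}

# exhaustive enumeration of all L^n equally likely sample paths
oracle_prob_complete <- function(L, n) {
  if (n == 0) return(as.numeric(L == 0))
  paths <- as.matrix(expand.grid(rep(list(seq_len(L)), n)))
  mean(apply(paths, 1, function(p) length(unique(p)) == L))
}

# per-position residue counting with nested loops
oracle_pfm <- function(variants) {
  len <- nchar(variants[1])
  res <- list()
  for (p in seq_len(len)) {
    counts <- setNames(rep(0, length(AMINO_ACIDS)), AMINO_ACIDS)
    for (v in variants) {
      r <- substr(v, p, p)
      counts[r] <- counts[r] + 1
    }
    res[[p]] <- counts / length(variants)
  }
  res
}

# frequency/E-score/ranking via plain loops over a named count vector
oracle_escore_ranking <- function(sel_counts, naive_counts, n_top) {
  fs <- sel_counts / sum(sel_counts)
  fn <- naive_counts / sum(naive_counts)
  es <- numeric(0)
  for (v in names(fs)) {
    if (fn[[v]] > 0) es[[v]] <- fs[[v]] / fn[[v]]
  }
  ord <- order(-unlist(es), names(es))
  names(es)[ord][seq_len(n_top)]
}

small_fastq <- function(path, sequences, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("r%03d", seq_along(sequences))
  lines <- as.vector(rbind(paste0("@", ids), sequences, "+",
                           strrep("I", nchar(sequences))))
  writeLines(lines, path)
  path
}
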