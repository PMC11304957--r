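# Coupon-collector mathematics behind the library-coverage guarantee: how
# many colonies must be sampled from an L-member library so that (nearly)
# every member is represented. Equal-abundance sampling is assumed; a
# Monte-Carlo mode quantifies the cost of uneven abundances.

#' Expected fraction of an L-member library covered by n samples
#'
#' Under equal-abundance sampling with replacement, each member is missed
#' with probability (1 - 1/L)^n, so the expected covered fraction is
#' 1 - (1 - 1/L)^n. Computed in log space for numerical stability at large n.
#'
#' @param L Library size (>= 1).
#' @param n Number of samples (>= 0).
#' @return Expected covered fraction in `[0, 1]`. Vectorised over `n`.
#' @examples
#' expected_coverage(8000, 150000)  # > 0.999
#' @export
expected_coverage <- function(L, n) {
  stopifnot(L >= 1, all(n >= 0))
  if (L == 1) return(ifelse(n >= 1, 1, 0))
  -expm1(n * log1p(-1 / L))
}

#' Probability that n samples cover an L-member library completely
#'
#' The strictest reading of "coverage": the probability that every one of the
#' L members appears at least once among n equal-probability draws. Computed
#' by inclusion-exclusion, P = sum_{j=0..L} (-1)^j C(L,j) (1 - j/L)^n, with
#' each term evaluated in log space and the alternating series truncated once
#' terms underflow; when even the leading correction underflows the union
#' bound 1 - L (1 - 1/L)^n is returned.
#'
#' @param L Library size (1 <= L <= 1e6).
#' @param n Number of samples.
#' @return Probability in `[0, 1]` (0 when `n < L`).
#' @examples
#' prob_complete_coverage(2, 2)        # 0.5
#' prob_complete_coverage(3, 3)        # 6/27
#' prob_complete_coverage(8000, 150000) # > 0.999
#' @export
prob_complete_coverage <- function(L, n) {
  stopifnot(L >= 1, n >= 0)
  if (L > 1e6) rlang::abort("L above the supported maximum (1e6)")
  if (n < L) return(0)
  if (L == 1) return(1)
  # log |term_j| = lchoose(L, j) + n * log(1 - j/L), j = 1..L-1
  j <- seq_len(L - 1L)
  logterm <- lchoose(L, j) + n * log1p(-j / L)
  keep <- logterm > log(.Machine$double.xmin) + 10
  if (!any(keep)) {
    return(max(0, -expm1(log(L) + n * log1p(-1 / L))))
  }
  j <- j[keep]
  logterm <- logterm[keep]
  # pair consecutive signed terms to limit cancellation, then sum ascending
  signs <- (-1)^j
  total <- sum(sort(signs * exp(logterm)))
  min(1, max(0, 1 + total))
}

#' Smallest sample size reaching a coverage target
#'
#' Binary search on the monotone coverage function for the least n with
#' coverage(L, n) >= target, under either the expected-fraction or the
#' complete-coverage definition.
#'
#' @param L Library size.
#' @param target Coverage target in (0, 1).
#' @param mode `"expected"` (expected covered fraction) or `"complete"`
#'   (probability every member is seen).
#' @return The minimal integer n.
#' @examples
#' required_sample_size(2, 0.5, "complete")  # 2
#' @export
required_sample_size <- function(L, target, mode = c("expected", "complete")) {
  mode <- match.arg(mode)
  stopifnot(L >= 1, target > 0, target < 1)
  f <- switch(mode,
    expected = function(n) expected_coverage(L, n),
    complete = function(n) prob_complete_coverage(L, n)
  )
  hi <- max(1L, L)
  while (f(hi) < target) hi <- hi * 2L
  lo <- 0L
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (f(mid) >= target) hi <- mid else lo <- mid
  }
  hi
}

#' Monte-Carlo complete coverage under uneven library abundances
#'
#' Estimates the probability of complete coverage when member abundances are
#' drawn from a symmetric Dirichlet instead of being equal, quantifying how
#' much unevenness erodes the equal-abundance guarantee.
#'
#' @param L Library size.
#' @param n Samples per draw.
#' @param concentration Symmetric Dirichlet concentration (smaller = more
#'   uneven; `Inf` recovers equal abundances).
#' @param n_sim Number of Monte-Carlo library draws.
#' @param seed Integer seed.
#' @return One-row tibble: `prob_complete` (mean over draws), `n_sim`.
#' @export
simulated_complete_coverage <- function(L, n, concentration = 5,
                                        n_sim = 200, seed = 1L) {
  with_stream(seed, 5L, {
    hits <- vapply(seq_len(n_sim), function(i) {
      p <- if (is.finite(concentration)) {
        g <- stats::rgamma(L, shape = concentration)
        g / sum(g)
      } else {
        rep(1 / L, L)
      }
      counts <- stats::rmultinom(1, n, p)
      all(counts > 0)
    }, logical(1))
  })
  tibble::tibble(prob_complete = mean(hits), n_sim = n_sim)
}
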