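#' Gene-set overlap enrichment: representation factor and hypergeometric tail
#'
#' For two gene sets of sizes `n1` and `n2` drawn from a universe of `N`
#' genes with observed overlap `k`, the expected overlap under independence
#' is `n1 * n2 / N` and the representation factor is `k / expected`
#' (RF > 1 means more overlap than expected for independent sets). The
#' hypergeometric tail is the one-sided upper-tail probability
#' `P(X >= k)` for `X ~ Hypergeometric(N, n1, n2)`, computed in log space.
#'
#' @param N universe size.
#' @param n1,n2 set sizes.
#' @param k observed overlap.
#' @return object of class `enrichment_result` with fields `N`, `n1`, `n2`,
#'   `k`, `expected`, `representation_factor`, `p_hypergeometric`.
#' @examples
#' representation_factor(14759, 227, 584, 29)
#' @export
representation_factor <- function(N, n1, n2, k) {
  svt_assert(is_count(N, 1L) && is_count(n1) && is_count(n2) && is_count(k),
             "config_error", "N, n1, n2, k must be non-negative counts")
  svt_assert(n1 <= N && n2 <= N, "config_error",
             "set sizes cannot exceed the universe")
  svt_assert(k <= min(n1, n2), "config_error",
             "overlap cannot exceed the smaller set")
  svt_assert(n1 > 0 && n2 > 0, "undefined_expectation",
             "expected overlap undefined when a set is empty")
  expected <- (n1 / N) * n2  # exact up to one rounding; n1*n2 may overflow int
  structure(list(
    N = N, n1 = n1, n2 = n2, k = k,
    expected = expected,
    representation_factor = k / expected,
    p_hypergeometric = hypergeometric_tail(N, n1, n2, k)
  ), class = "enrichment_result")
}

#' @rdname representation_factor
#' @export
hypergeometric_tail <- function(N, n1, n2, k) {
  svt_assert(is_count(N, 1L) && is_count(n1) && is_count(n2) && is_count(k),
             "config_error", "N, n1, n2, k must be non-negative counts")
  svt_assert(n1 <= N && n2 <= N, "config_error",
             "set sizes cannot exceed the universe")
  if (k > min(n1, n2)) {
    warning("observed overlap ", k, " exceeds min(n1, n2); impossible, P = 0")
    return(0)
  }
  if (k == 0L) return(1)
  ## P(X >= k) via the stable log-space survival function
  exp(stats::phyper(k - 1, n1, N - n1, n2, lower.tail = FALSE, log.p = TRUE))
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result>\n")
  cat("  universe ", x$N, "; set1 ", x$n1, "; set2 ", x$n2,
      "; overlap ", x$k, "\n", sep = "")
  cat("  expected overlap: ", format(round(x$expected, 3)),
      "; representation factor: ", format(round(x$representation_factor, 1)),
      "\n", sep = "")
  cat("  P(X >= k) = ", format(x$p_hypergeometric, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Permutation null for gene-set overlap
#'
#' Draws `reps` random subsets of size `draw_size` from the universe
#' (uniformly, without replacement), records the overlap of each draw with
#' `fixed_set`, and summarises the null distribution with min, quartiles
#' (type-7 linear interpolation, the standard summary convention), mean and
#' max.
#'
#' @param universe character vector of gene ids.
#' @param fixed_set subset of `universe`.
#' @param draw_size size of each random draw.
#' @param reps number of draws (default 1000).
#' @param seed PRNG seed.
#' @return object of class `permutation_summary` with the summary fields
#'   and the raw `overlaps` vector.
#' @export
permutation_overlap <- function(universe, fixed_set, draw_size, reps = 1000L,
                                seed = 1L) {
  universe <- as.character(universe)
  fixed_set <- as.character(fixed_set)
  svt_assert(!anyDuplicated(universe), "config_error",
             "universe contains duplicate ids")
  svt_assert(all(fixed_set %in% universe), "set_membership_error",
             "fixed_set is not a subset of the universe")
  svt_assert(is_count(draw_size) && draw_size <= length(universe),
             "config_error", "draw_size must be a count <= |universe|")
  svt_assert(is_count(reps, 1L), "config_error", "reps must be >= 1")
  in_fixed <- universe %in% fixed_set
  n <- length(universe)
  overlaps <- with_seed(seed, vapply(seq_len(reps), function(i) {
    sum(in_fixed[sample.int(n, draw_size)])
  }, numeric(1L)))
  q <- stats::quantile(overlaps, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(
    reps = as.integer(reps), draw_size = as.integer(draw_size),
    min = min(overlaps), q1 = q[1L], median = q[2L], mean = mean(overlaps),
    q3 = q[3L], max = max(overlaps), rng_seed = seed, overlaps = overlaps
  ), class = "permutation_summary")
}

#' @export
print.permutation_summary <- function(x, ...) {
  cat("<permutation_summary> ", x$reps, " draws of ", x$draw_size, "\n",
      sep = "")
  cat(sprintf("  Min: %.3f; 1st Qu.: %.3f; Median: %.3f; Mean: %.3f; 3rd Qu.: %.3f; Max: %.3f\n",
              x$min, x$q1, x$median, x$mean, x$q3, x$max))
  invisible(x)
}

#' Overlap enrichment of two explicit gene sets
#'
#' Computes the observed overlap `k = |A` \eqn{\cap} `B|` and delegates to
#' [representation_factor()] / [hypergeometric_tail()].
#'
#' @param setA,setB character vectors of gene ids, subsets of `universe`.
#' @param universe character vector of gene ids.
#' @return an `enrichment_result`.
#' @export
target_set_overlap <- function(setA, setB, universe) {
  universe <- as.character(universe)
  setA <- unique(as.character(setA)); setB <- unique(as.character(setB))
  svt_assert(all(setA %in% universe) && all(setB %in% universe),
             "set_membership_error", "sets must be subsets of the universe")
  representation_factor(length(universe), length(setA), length(setB),
                        length(intersect(setA, setB)))
}
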