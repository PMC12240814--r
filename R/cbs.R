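# Circular binary segmentation with permutation significance.

#' Segment a series with circular binary segmentation
#'
#' Recursively finds the circular arc maximizing the two-sample t-like
#' statistic between arc and complement; a split is accepted when its
#' permutation p-value (over `n_perm` within-segment shuffles) is below
#' `alpha_find`. After the recursion, every retained changepoint is
#' re-validated against its two flanking segments with a two-sample
#' permutation test at `alpha_validate` and dropped on failure (iterated to a
#' fixed point, since dropping a changepoint widens its neighbors' flanks).
#' Deterministic given `(series, seed)`: each segment's permutations are
#' seeded from the run seed plus a segment counter.
#'
#' @param x Numeric series (e.g. Anscombe-transformed copy-number ratios).
#' @param alpha_find Significance threshold for the recursive search
#'   (default 0.05).
#' @param alpha_validate Threshold for changepoint validation (default 0.01).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return Integer vector of changepoint indices: position `b` means a
#'   boundary between `x[b]` and `x[b + 1]`. Empty for short or constant
#'   series.
#' @export
cbs_segment <- function(x, alpha_find = 0.05, alpha_validate = 0.01,
                        n_perm = 1000, seed = 1) {
  n <- length(x)
  if (n < 4L) return(integer(0))
  boundaries <- integer(0)
  counter <- 0L

  recurse <- function(lo, hi) {
    m <- hi - lo + 1L
    if (m < 4L) return()
    counter <<- counter + 1L
    set.seed(seed + counter)
    res <- cbs_max_stat_cpp(x[lo:hi])
    if (res$stat <= 0) return()
    perms <- cbs_perm_stats_cpp(x[lo:hi], n_perm)
    p <- (sum(perms >= res$stat - 1e-12) + 1) / (n_perm + 1)
    if (p >= alpha_find) return()
    i <- res$i; j <- res$j  # 0-based boundaries within the segment
    if (i > 0L) boundaries <<- c(boundaries, lo + i - 1L)
    if (j < m) boundaries <<- c(boundaries, lo + j - 1L)
    if (i > 0L) recurse(lo, lo + i - 1L)
    recurse(lo + i, lo + j - 1L)
    if (j < m) recurse(lo + j, hi)
  }
  recurse(1L, n)
  cps <- sort(unique(boundaries))

  # validation against flanking segments: re-test every retained changepoint
  # and drop the worst failure, one per pass, since removing a changepoint
  # widens its neighbors' flanks and changes their tests
  repeat {
    if (length(cps) == 0L) break
    edges <- c(0L, cps, n)
    pvals <- vapply(seq_along(cps), function(k) {
      left <- x[(edges[k] + 1L):cps[k]]
      right <- x[(cps[k] + 1L):edges[k + 2L]]
      counter <<- counter + 1L
      set.seed(seed + 100000L + counter)
      two_sample_perm_pvalue_cpp(c(left, right), length(left), n_perm)
    }, double(1))
    failing <- which(pvals >= alpha_validate)
    if (!length(failing)) break
    cps <- cps[-failing[which.max(pvals[failing])]]
  }
  cps
}
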