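# Shared low-level helpers: CIGAR arithmetic, chained clustering, checks.

# Tokenize CIGAR strings into per-record tibbles of (op, len).
cigar_ops <- function(cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  purrr::map2(ops, lens, function(o, l) fast_tbl(op = o, len = l))
}

# Reference-consuming length of a CIGAR (M, D, N, =, X).
cigar_ref_len <- function(cigar) {
  vapply(
    cigar_ops(cigar),
    function(x) sum(x$len[x$op %in% c("M", "D", "N", "=", "X")]),
    integer(1)
  )
}

# Query-consuming length excluding clips (M, I, =, X).
cigar_aligned_query_len <- function(cigar) {
  vapply(
    cigar_ops(cigar),
    function(x) sum(x$len[x$op %in% c("M", "I", "=", "X")]),
    integer(1)
  )
}

cigar_clips <- function(cigar) {
  ops <- cigar_ops(cigar)
  lead <- vapply(ops, function(x) {
    if (nrow(x) && x$op[1] %in% c("S", "H")) x$len[1] else 0L
  }, integer(1))
  trail <- vapply(ops, function(x) {
    n <- nrow(x)
    if (n && x$op[n] %in% c("S", "H")) x$len[n] else 0L
  }, integer(1))
  fast_tbl(lead = lead, trail = trail)
}

# Offsets of the aligned part of a segment on the original (unaligned-strand)
# read: 0-based half-open [query_start, query_end). For a minus-strand
# alignment the leading clip in the CIGAR sits at the END of the original
# read, so the roles of the clips swap.
cigar_query_span <- function(cigar, strand) {
  clips <- cigar_clips(cigar)
  alen <- cigar_aligned_query_len(cigar)
  qs <- ifelse(strand == "+", clips$lead, clips$trail)
  fast_tbl(query_start = as.integer(qs), query_end = as.integer(qs + alen))
}

# Single-linkage chaining: positions must be sorted non-decreasingly within
# each group; a value opens a new cluster when it is more than `window` from
# the previous value. Returns an integer cluster index.
chain_ids <- function(pos, window) {
  if (length(pos) == 0L) return(integer(0))
  if (is.unsorted(pos)) abort("chain_ids() requires sorted positions")
  cumsum(c(TRUE, diff(pos) > window))
}

# Relative-gap chaining for insertion sizes: split when consecutive sorted
# sizes differ by more than rel_tol * the smaller size.
chain_ids_relative <- function(sizes, rel_tol) {
  if (length(sizes) == 0L) return(integer(0))
  if (is.unsorted(sizes)) abort("chain_ids_relative() requires sorted sizes")
  gaps <- diff(sizes)
  lower <- head(sizes, -1L)
  cumsum(c(TRUE, gaps > rel_tol * lower))
}

# Low-overhead tibble constructor for hot per-read paths: recycles length-1
# values, skips tibble()'s quosure machinery.
fast_tbl <- function(...) {
  l <- list(...)
  n <- max(lengths(l))
  l <- lapply(l, function(v) if (length(v) == n) v else rep_len(v, n))
  tibble::new_tibble(l, nrow = n)
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(paste0(what, " is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Median with deterministic lower-median tie-break for even-length integer
# vectors (cluster representative positions).
median_low <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sort(x)[ceiling(n / 2)]
}

sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

`%||%` <- rlang::`%||%`
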