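# Somatic copy-number aberration detection: genome binning, read counting,
# log2-ratio normalization, outlier smoothing, variance stabilization, CBS
# segmentation and merging of over-segmented output.

#' Tile the genome into copy-number bins
#'
#' Builds non-overlapping bins of `bin_size` bp across every contig,
#' truncating terminal bins at contig ends. When somatic breakpoint positions
#' are given, any bin containing one is split at that position so segment
#' boundaries can coincide with SV breakends.
#'
#' @param contig_lengths Named integer vector.
#' @param bin_size Bin size in bp (default 10000).
#' @param breakpoints Optional tibble of breakend positions (`contig`,
#'   `pos`, 0-based) from PASS SV calls.
#' @return Tibble of bins (`contig`, `start`, `end`), 0-based half-open.
#' @export
build_bins <- function(contig_lengths, bin_size = 10000, breakpoints = NULL) {
  out <- imap(as.list(contig_lengths), function(len, ctg) {
    bounds <- unique(c(seq(0L, len, by = bin_size), len))
    if (!is.null(breakpoints)) {
      bp <- breakpoints$pos[breakpoints$contig == ctg &
                              breakpoints$pos > 0 & breakpoints$pos < len]
      bounds <- sort(unique(c(bounds, bp)))
    }
    tibble(contig = ctg, start = as.integer(head(bounds, -1L)),
           end = as.integer(tail(bounds, -1L)))
  })
  list_rbind(out)
}

interval_overlap_fraction <- function(bins, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) {
    return(rep(0, nrow(bins)))
  }
  vapply(seq_len(nrow(bins)), function(i) {
    sel <- intervals$contig == bins$contig[i]
    if (!any(sel)) return(0)
    ov <- pmax(0, pmin(intervals$end[sel], bins$end[i]) -
                 pmax(intervals$start[sel], bins$start[i]))
    min(sum(ov) / (bins$end[i] - bins$start[i]), 1)
  }, double(1))
}

#' Annotate bins excluded from copy-number analysis
#'
#' Marks bins with more than `blacklist_max` overlap with blacklisted regions
#' and bins whose reference-N fraction exceeds `n_max`. Zero-count bins are
#' removed later, after counting (see [normalize_log2()]).
#'
#' @param bins Bin tibble.
#' @param blacklist Optional interval tibble (`contig`, `start`, `end`).
#' @param n_fraction Optional numeric vector (per bin) of reference N-base
#'   fractions; 0 when absent.
#' @param blacklist_max Maximum tolerated blacklist overlap (default 0.05).
#' @param n_max Maximum tolerated N fraction (default 0.75).
#' @return Bins with `excluded` (logical) and `excluded_reason` columns.
#' @export
filter_bins <- function(bins, blacklist = NULL, n_fraction = NULL,
                        blacklist_max = 0.05, n_max = 0.75) {
  bl_frac <- interval_overlap_fraction(bins, blacklist)
  n_frac <- n_fraction %||% rep(0, nrow(bins))
  stopifnot(length(n_frac) == nrow(bins))
  bins |>
    mutate(
      excluded_reason = dplyr::case_when(
        bl_frac > blacklist_max ~ "blacklist",
        n_frac > n_max ~ "n_fraction",
        TRUE ~ NA_character_
      ),
      excluded = !is.na(.data$excluded_reason)
    )
}

#' Count reads per copy-number bin
#'
#' Each primary alignment with mapping quality of at least `min_mapq`
#' increments the bin containing its alignment start (half-open convention:
#' a read starting on a boundary belongs to the right-hand bin).
#' Supplementary records are not counted.
#'
#' @param alignments Alignment-record tibble (may mix tumor and normal rows;
#'   the `sample` column routes counts).
#' @param bins Bin tibble.
#' @param min_mapq Minimum mapping quality (default 5).
#' @return Bins with `tumor_count` and `normal_count` columns.
#' @export
count_reads <- function(alignments, bins, min_mapq = 5) {
  use <- filter(alignments, !.data$is_supplementary, .data$mapq >= min_mapq)
  count_for <- function(samp) {
    cnt <- integer(nrow(bins))
    al <- filter(use, .data$sample == samp)
    for (ctg in unique(bins$contig)) {
      bi <- which(bins$contig == ctg)
      st <- al$start[al$contig == ctg]
      if (!length(st)) next
      idx <- findInterval(st, bins$start[bi])
      ok <- idx >= 1L & st < bins$end[bi][pmax(idx, 1L)]
      cnt[bi] <- cnt[bi] + tabulate(idx[ok], nbins = length(bi))
    }
    cnt
  }
  bins |>
    mutate(tumor_count = count_for("tumor"),
           normal_count = count_for("normal"))
}

#' Compute log2 copy-number ratios per bin
#'
#' Paired mode normalizes tumor counts by matched-normal counts, correcting
#' for the depth difference: `log2R = log2((t/n) * (sum(n)/sum(t)))`.
#' Tumor-only mode self-normalizes by the median count over retained bins:
#' `log2R = log2(t / median(t))`. Bins without counts (and, in paired mode,
#' bins with a zero normal count) are removed as `zero_count` rather than
#' producing infinities.
#'
#' @param bins Counted bin tibble (from [count_reads()] or a synthetic bin
#'   table), optionally carrying `excluded` annotations from [filter_bins()].
#' @param mode `"paired"` or `"tumor_only"`.
#' @return Retained bins with a `log2r` column, ordered by contig and start.
#' @export
normalize_log2 <- function(bins, mode = c("paired", "tumor_only")) {
  mode <- match.arg(mode)
  if (!"excluded" %in% names(bins)) {
    bins <- mutate(bins, excluded = FALSE, excluded_reason = NA_character_)
  }
  keep <- filter(bins, !.data$excluded)
  if (mode == "paired") {
    assert_columns(keep, c("tumor_count", "normal_count"), "bin table")
    keep <- filter(keep, .data$tumor_count > 0, .data$normal_count > 0)
    scale <- sum(keep$normal_count) / sum(keep$tumor_count)
    keep <- mutate(keep, log2r = log2((.data$tumor_count /
                                         .data$normal_count) * scale))
  } else {
    keep <- filter(keep, .data$tumor_count > 0)
    med <- stats::median(keep$tumor_count)
    keep <- mutate(keep, log2r = log2(.data$tumor_count / med))
  }
  arrange(keep, .data$contig, .data$start)
}

#' Smooth single-point outliers in a log2R series
#'
#' A point is replaced by the median of its two-bin neighborhood iff it
#' deviates from that median by more than twice the series' median absolute
#' deviation AND both immediate neighbors lie strictly on the same side of
#' it — the signature of an isolated spike. Runs of two or more deviating
#' points are left untouched, since they may be a real short segment.
#'
#' @param x Numeric log2R series (one contig, positionally ordered).
#' @return Smoothed series of the same length.
#' @export
smooth_outliers <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  madx <- stats::mad(x)
  out <- x
  for (i in 2:(n - 1)) {
    nb <- x[max(1, i - 2):min(n, i + 2)]
    med <- stats::median(nb)
    single <- (x[i - 1] < x[i] && x[i + 1] < x[i]) ||
      (x[i - 1] > x[i] && x[i + 1] > x[i])
    if (single && abs(x[i] - med) > 2 * madx) out[i] <- med
  }
  out
}

#' Anscombe variance stabilization of copy-number ratios
#'
#' Applies `A(r) = 2 * sqrt(r + 3/8)` on the ratio scale `r = 2^log2R`
#' (the log scale can be negative, where the transform is undefined).
#' Segmentation runs on `A(r)`; segment means are reported back on the log2R
#' scale as the mean of member bins' log2R.
#'
#' @param log2r Numeric log2R series.
#' @return Transformed series.
#' @export
variance_stabilize <- function(log2r) {
  2 * sqrt(2^log2r + 3 / 8)
}

#' Merge over-segmented copy-number segments
#'
#' The merge threshold is the 20th percentile (linear interpolation) of the
#' absolute log2R difference over all segment pairs genome-wide; adjacent
#' same-contig segments whose difference is strictly below it (or exactly
#' zero) are merged, means recomputed, and the pass repeated until a fixed
#' point.
#'
#' @param segments Segment tibble (`contig`, `start`, `end`, `n_bins`,
#'   `mean_log2r`).
#' @return Merged segment tibble.
#' @export
merge_segments <- function(segments) {
  if (nrow(segments) < 2L) return(segments)
  repeat {
    if (nrow(segments) < 2L) break
    deltas <- abs(outer(segments$mean_log2r, segments$mean_log2r, "-"))
    deltas <- deltas[upper.tri(deltas)]
    if (!length(deltas)) break
    threshold <- unname(stats::quantile(deltas, 0.20, type = 7))
    merged_any <- FALSE
    i <- 1L
    while (i < nrow(segments)) {
      same <- segments$contig[i] == segments$contig[i + 1L]
      d <- abs(segments$mean_log2r[i] - segments$mean_log2r[i + 1L])
      if (same && (d == 0 || d < threshold)) {
        w <- c(segments$n_bins[i], segments$n_bins[i + 1L])
        segments$mean_log2r[i] <-
          sum(w * segments$mean_log2r[i:(i + 1L)]) / sum(w)
        segments$end[i] <- segments$end[i + 1L]
        segments$n_bins[i] <- sum(w)
        segments <- segments[-(i + 1L), ]
        merged_any <- TRUE
      } else {
        i <- i + 1L
      }
    }
    if (!merged_any) break
  }
  segments
}

#' Segment a normalized bin table into copy-number segments
#'
#' Per contig: smooth single-point outliers, Anscombe-transform the ratios,
#' run permutation-tested CBS, convert bin-index changepoints to genomic
#' positions, and merge over-segmented output genome-wide.
#'
#' @param bins Normalized bin tibble (from [normalize_log2()]).
#' @param alpha_find,alpha_validate,n_perm CBS parameters (defaults 0.05,
#'   0.01, 1000).
#' @param seed Integer seed.
#' @param merge Merge over-segmented output (default TRUE).
#' @return A list with `segments` (tibble: `contig`, `start`, `end`,
#'   `n_bins`, `size`, `mean_log2r`) and `changepoints` (tibble: `contig`,
#'   `pos`).
#' @export
segment_copy_number <- function(bins, alpha_find = 0.05,
                                alpha_validate = 0.01, n_perm = 1000,
                                seed = 1, merge = TRUE) {
  assert_columns(bins, c("contig", "start", "end", "log2r"), "bin table")
  seg_list <- list()
  cp_list <- list()
  contig_i <- 0L
  for (ctg in unique(bins$contig)) {
    contig_i <- contig_i + 1L
    b <- arrange(filter(bins, .data$contig == ctg), .data$start)
    x <- smooth_outliers(b$log2r)
    a <- variance_stabilize(x)
    cps <- cbs_segment(a, alpha_find = alpha_find,
                       alpha_validate = alpha_validate, n_perm = n_perm,
                       seed = seed + 1000L * contig_i)
    edges <- c(0L, cps, nrow(b))
    for (k in seq_len(length(edges) - 1L)) {
      idx <- (edges[k] + 1L):edges[k + 1L]
      seg_list[[length(seg_list) + 1L]] <- tibble(
        contig = ctg, start = b$start[idx[1]], end = b$end[idx[length(idx)]],
        n_bins = length(idx), mean_log2r = mean(b$log2r[idx])
      )
    }
    if (length(cps)) {
      cp_list[[length(cp_list) + 1L]] <- tibble(contig = ctg,
                                                pos = b$end[cps])
    }
  }
  segments <- list_rbind(seg_list)
  if (merge) segments <- merge_segments(segments)
  segments <- mutate(segments, size = .data$end - .data$start)
  changepoints <- if (length(cp_list)) list_rbind(cp_list) else
    tibble(contig = character(), pos = integer())
  # changepoints surviving the merge
  kept <- segments |>
    group_by(.data$contig) |>
    reframe(pos = head(.data$end, -1L))
  changepoints <- dplyr::semi_join(changepoints, kept,
                                   by = c("contig", "pos"))
  list(segments = segments, changepoints = changepoints)
}
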