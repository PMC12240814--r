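# Per-haplotype coverage tracks: one vector of alignment-overlap counts per
# (contig, haplotype), at a small bin size (default 5 bp) so breakpoint-level
# depth queries stay cheap.

HAP_LEVELS <- c("hap1", "hap2", "unphased")

#' Build a per-haplotype coverage track
#'
#' Every alignment record (primary and supplementary) increments by one each
#' bin it overlaps, in the vector of its haplotype (`HP` tag 1, 2, or
#' unphased). Vector length is `ceiling(contig_length / bin_size)`.
#'
#' @param records Alignment-record or segment tibble with `contig`, `start`,
#'   `end`, `haplotype` columns (0-based half-open coordinates).
#' @param contig_lengths Named integer vector of contig lengths.
#' @param bin_size Bin size in bp (default 5).
#' @return A `coverage_track` object.
#' @export
build_coverage <- function(records, contig_lengths, bin_size = 5) {
  stopifnot(bin_size >= 1)
  counts <- lapply(contig_lengths, function(len) {
    nb <- ceiling(len / bin_size)
    matrix(0L, nrow = 3L, ncol = nb, dimnames = list(HAP_LEVELS, NULL))
  })
  if (nrow(records) > 0L) {
    hap_row <- ifelse(is.na(records$haplotype), 3L,
                      ifelse(records$haplotype == 1L, 1L, 2L))
    b0 <- floor(records$start / bin_size) + 1L
    b1 <- floor((records$end - 1L) / bin_size) + 1L
    for (ctg in unique(records$contig)) {
      if (!ctg %in% names(counts)) {
        abort(paste0("record on unknown contig: ", ctg))
      }
      sel <- which(records$contig == ctg)
      nb <- ncol(counts[[ctg]])
      for (h in 1:3) {
        hsel <- sel[hap_row[sel] == h]
        if (!length(hsel)) next
        # difference-array accumulation: +1 at the first bin, -1 after the
        # last, then cumulative sum
        lo <- pmax(b0[hsel], 1L)
        hi <- pmin(b1[hsel], nb)
        d <- tabulate(lo, nbins = nb + 1L) -
          tabulate(hi + 1L, nbins = nb + 1L)
        counts[[ctg]][h, ] <- counts[[ctg]][h, ] +
          cumsum(d[seq_len(nb)])
      }
    }
  }
  structure(
    list(bin_size = bin_size, contig_lengths = contig_lengths,
         counts = counts),
    class = "coverage_track"
  )
}

#' Query a coverage track at a position
#'
#' @param track A `coverage_track`.
#' @param contig Contig name.
#' @param position 0-based position.
#' @return A one-row tibble with `hap1`, `hap2`, `unphased` counts and their
#'   `total` at the bin containing `position`.
#' @export
coverage_at <- function(track, contig, position) {
  if (!contig %in% names(track$counts)) {
    abort(paste0("unknown contig: ", contig))
  }
  if (position < 0 || position >= track$contig_lengths[[contig]]) {
    abort(paste0("position ", position, " outside contig ", contig))
  }
  bin <- floor(position / track$bin_size) + 1L
  v <- track$counts[[contig]][, bin]
  tibble(hap1 = v[["hap1"]], hap2 = v[["hap2"]], unphased = v[["unphased"]],
         total = sum(v))
}

# Depth (total) at a clamped position; 0-depth outside known contigs so
# feature encoding never errors on sentinel loci.
coverage_total_at <- function(track, contig, position) {
  if (is.na(contig) || !contig %in% names(track$counts)) return(0)
  len <- track$contig_lengths[[contig]]
  pos <- min(max(position, 0), len - 1)
  sum(track$counts[[contig]][, floor(pos / track$bin_size) + 1L])
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track> bin size", x$bin_size, "bp;",
      length(x$counts), "contig(s)\n")
  invisible(x)
}
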