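# Alignment I/O. Alignment records live in ordinary tibbles with one row per
# mapped record (primary or supplementary) so that every downstream stage can
# be driven either from a BAM/CRAM file or from in-memory synthetic data.
#
# Coordinates are 0-based half-open throughout the package; conversion to
# 1-based happens only at VCF/SAM emission.

ALIGNMENT_COLS <- c(
  "read_name", "contig", "start", "end", "strand", "mapq", "cigar",
  "is_supplementary", "haplotype", "phase_set", "sample", "seq", "sa_tag"
)

#' Validate an alignment-record tibble
#'
#' Checks the column contract shared by all functions consuming alignment
#' records and the per-record invariants (`start < end`, reference-consuming
#' CIGAR length equal to `end - start`).
#'
#' @param records A tibble of alignment records.
#' @return `records`, invisibly.
#' @export
validate_alignments <- function(records) {
  assert_columns(records, ALIGNMENT_COLS, "alignment records")
  if (nrow(records) == 0L) return(invisible(records))
  if (any(records$start >= records$end)) {
    abort("alignment records must satisfy start < end")
  }
  reflen <- cigar_ref_len(records$cigar)
  if (any(reflen != records$end - records$start)) {
    abort("CIGAR reference length must equal end - start")
  }
  if (!all(records$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'")
  }
  invisible(records)
}

effective_mapq_threshold <- function(sample_role, min_mapq,
                                     normal_leniency_fraction) {
  if (sample_role == "normal") min_mapq * normal_leniency_fraction else min_mapq
}

#' Read alignment records from a BAM/CRAM file
#'
#' Reads primary and supplementary alignments whose mapping quality passes the
#' sample's effective threshold. For the matched normal the threshold is
#' relaxed by `normal_leniency_fraction` (default 0.5, so with `min_mapq = 5`
#' normal records with MAPQ >= 2.5 are kept) so that germline evidence is not
#' missed when discounting somatic calls. Unmapped, secondary and
#' duplicate-flagged records are always excluded. The threshold comparison is
#' done on the real-valued effective threshold; no rounding.
#'
#' @param path Path to a coordinate-sorted, indexed BAM or CRAM file.
#' @param region Optional region string `"contig"` or `"contig:start-end"`
#'   (1-based inclusive, as in samtools).
#' @param sample_role `"tumor"` or `"normal"`.
#' @param min_mapq Minimum mapping quality (default 5).
#' @param normal_leniency_fraction Multiplier applied to `min_mapq` for the
#'   normal sample (default 0.5).
#' @return A tibble of alignment records (0-based half-open coordinates) with
#'   haplotype (`HP`), phase set (`PS`) and supplementary-alignment (`SA`)
#'   tags when present.
#' @export
read_alignments <- function(path, region = NULL,
                            sample_role = c("tumor", "normal"),
                            min_mapq = 5, normal_leniency_fraction = 0.5) {
  sample_role <- match.arg(sample_role)
  stopifnot(min_mapq >= 0, normal_leniency_fraction > 0,
            normal_leniency_fraction <= 1)
  if (!file.exists(path)) abort(paste0("alignment file not found: ", path))
  index <- paste0(path, ".bai")
  if (!file.exists(index) && !file.exists(sub("\\.bam$", ".bai", path)) &&
      !file.exists(paste0(path, ".crai"))) {
    abort(paste0("alignment index not found for: ", path))
  }

  hdr <- Rsamtools::scanBamHeader(path)[[1]]$targets
  which <- NULL
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+)(?::([0-9]+)-([0-9]+))?$", region))[[1]]
    contig <- m[2]
    if (!contig %in% names(hdr)) {
      abort(paste0("contig not present in alignment header: ", contig))
    }
    rstart <- if (!is.na(m[3]) && nzchar(m[3])) as.integer(m[3]) else 1L
    rend <- if (!is.na(m[4]) && nzchar(m[4])) as.integer(m[4]) else
      unname(hdr[contig])
    which <- GenomicRanges::GRanges(contig, IRanges::IRanges(rstart, rend))
  }

  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isDuplicate = FALSE
  )
  param_args <- list(
    flag = flag,
    what = c("qname", "rname", "strand", "pos", "mapq", "cigar", "flag", "seq"),
    tag = c("SA", "HP", "PS")
  )
  if (!is.null(which)) param_args$which <- which
  param <- do.call(Rsamtools::ScanBamParam, param_args)
  res <- Rsamtools::scanBam(path, param = param)[[1]]

  n <- length(res$qname)
  if (n == 0L) return(empty_alignments())
  seqs <- as.character(res$seq)
  seqs[seqs == ""] <- NA_character_
  records <- tibble(
    read_name = res$qname,
    contig = as.character(res$rname),
    start = res$pos - 1L,
    end = res$pos - 1L + cigar_ref_len(res$cigar),
    strand = as.character(res$strand),
    mapq = res$mapq,
    cigar = res$cigar,
    is_supplementary = bitwAnd(res$flag, 2048L) > 0L,
    haplotype = as.integer(res$tag$HP %||% rep(NA_integer_, n)),
    phase_set = as.integer(res$tag$PS %||% rep(NA_integer_, n)),
    sample = sample_role,
    seq = seqs,
    sa_tag = as.character(res$tag$SA %||% rep(NA_character_, n))
  )
  threshold <- effective_mapq_threshold(sample_role, min_mapq,
                                        normal_leniency_fraction)
  records <- filter(records, .data$mapq >= threshold)
  arrange(records, .data$contig, .data$start)
}

empty_alignments <- function() {
  tibble(
    read_name = character(), contig = character(), start = integer(),
    end = integer(), strand = character(), mapq = integer(),
    cigar = character(), is_supplementary = logical(),
    haplotype = integer(), phase_set = integer(), sample = character(),
    seq = character(), sa_tag = character()
  )
}

#' Apply the sample-aware mapping-quality gate to in-memory records
#'
#' Same gate as [read_alignments()] but for alignment tibbles that never
#' touched disk (synthetic data, replicate splits).
#'
#' @inheritParams read_alignments
#' @param records Alignment-record tibble.
#' @return The gated tibble.
#' @export
filter_alignments <- function(records, sample_role = c("tumor", "normal"),
                              min_mapq = 5, normal_leniency_fraction = 0.5) {
  sample_role <- match.arg(sample_role)
  threshold <- effective_mapq_threshold(sample_role, min_mapq,
                                        normal_leniency_fraction)
  filter(records, .data$mapq >= threshold)
}

#' Write alignment records to an indexed BAM file
#'
#' Serializes an alignment tibble to SAM and converts it to a
#' coordinate-sorted, indexed BAM with Rsamtools. Records without stored
#' sequence are written with `SEQ = *`.
#'
#' @param records Alignment-record tibble.
#' @param path Output BAM path (`.bam`).
#' @param contig_lengths Named integer vector of contig lengths.
#' @return The BAM path, invisibly.
#' @export
write_alignments <- function(records, path, contig_lengths) {
  validate_alignments(records)
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam), add = TRUE)
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    paste0("@SQ\tSN:", names(contig_lengths), "\tLN:", as.integer(contig_lengths))
  )
  flag <- ifelse(records$strand == "-", 16L, 0L) +
    ifelse(records$is_supplementary, 2048L, 0L)
  opt <- rep("", nrow(records))
  has_sa <- !is.na(records$sa_tag)
  opt[has_sa] <- paste0(opt[has_sa], "\tSA:Z:", records$sa_tag[has_sa])
  has_hp <- !is.na(records$haplotype)
  opt[has_hp] <- paste0(opt[has_hp], "\tHP:i:", records$haplotype[has_hp])
  has_ps <- !is.na(records$phase_set)
  opt[has_ps] <- paste0(opt[has_ps], "\tPS:i:", records$phase_set[has_ps])
  seq <- ifelse(is.na(records$seq), "*", records$seq)
  body <- paste0(
    records$read_name, "\t", flag, "\t", records$contig, "\t",
    records$start + 1L, "\t", records$mapq, "\t", records$cigar,
    "\t*\t0\t0\t", seq, "\t*", opt
  )
  writeLines(c(header, body), sam)
  dest <- sub("\\.bam$", "", path)
  bam <- Rsamtools::asBam(sam, destination = dest, overwrite = TRUE,
                          indexDestination = TRUE)
  invisible(bam)
}

#' Read genomic intervals from a BED file
#'
#' BED is 0-based half-open; intervals are validated (`start <= end`) and
#' returned sorted. Overlapping intervals are preserved, never auto-merged.
#'
#' @param path Path to a BED file (3+ columns, optional 4th label column).
#' @return A tibble with `contig`, `start`, `end`, `label`.
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) abort(paste0("BED file not found: ", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  label = character()))
  }
  fields <- strsplit(lines, "\t| +")
  out <- tibble(
    contig = map_chr(fields, 1),
    start = as.integer(map_chr(fields, 2)),
    end = as.integer(map_chr(fields, 3)),
    label = map_chr(fields, function(f) if (length(f) >= 4) f[4] else NA_character_)
  )
  bad <- which(out$start > out$end)
  if (length(bad)) {
    abort(paste0("BED interval with start > end at line ", bad[1]))
  }
  arrange(out, .data$contig, .data$start, .data$end)
}

#' Read heterozygous SNP sites from a VCF or TSV file
#'
#' Accepts a (possibly header-less) VCF, in which case `CHROM/POS/REF/ALT`
#' are used, or a tab-separated table with columns
#' `contig`, `position`, `ref_allele`, `alt_allele`.
#'
#' @param path Input path.
#' @param source Provenance label, `"matched_germline"` or
#'   `"population_panel"`.
#' @return A tibble of SNP sites with 1-based `position`, sorted.
#' @export
read_snp_sites <- function(path,
                           source = c("matched_germline", "population_panel")) {
  source <- match.arg(source)
  if (!file.exists(path)) abort(paste0("SNP file not found: ", path))
  lines <- readLines(path)
  is_vcf <- any(grepl("^##fileformat=VCF", lines)) || grepl("\\.vcf$", path)
  if (is_vcf) {
    body <- lines[!grepl("^#", lines) & nzchar(lines)]
    fields <- strsplit(body, "\t")
    out <- tibble(
      contig = map_chr(fields, 1),
      position = as.integer(map_chr(fields, 2)),
      ref_allele = map_chr(fields, 4),
      alt_allele = map_chr(fields, 5)
    )
  } else {
    out <- as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                       stringsAsFactors = FALSE))
    assert_columns(out, c("contig", "position", "ref_allele", "alt_allele"),
                   "SNP table")
    out <- select(out, "contig", "position", "ref_allele", "alt_allele")
    out$position <- as.integer(out$position)
  }
  if (any(out$ref_allele == out$alt_allele)) {
    abort("SNP sites must have ref_allele != alt_allele")
  }
  out$source <- source
  arrange(out, .data$contig, .data$position)
}
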