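# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

shared_model <- function() {
  cached_fixture("model", function() fit_default_model(seed = 2))
}

shared_worked_example <- function() {
  cached_fixture("wx", function() make_worked_example(seed = 1))
}

shared_worked_run <- function() {
  cached_fixture("wx_run", function() {
    wx <- shared_worked_example()
    run_pipeline(wx$tumor, wx$normal, wx$contig_lengths,
                 model = shared_model(), cn_bins = wx$cn$bins,
                 baf = wx$cn$baf, params = list(block_size = wx$block_size),
                 seed = 11)
  })
}

# One alignment record row with sensible defaults.
record_row <- function(read_name = "r1", contig = "chr1", start = 1000L,
                       cigar = "100M", strand = "+", mapq = 60L,
                       is_supplementary = FALSE, haplotype = NA_integer_,
                       phase_set = NA_integer_, sample = "tumor",
                       seq = NA_character_, sa_tag = NA_character_) {
  tibble::tibble(
    read_name = read_name, contig = contig, start = as.integer(start),
    end = as.integer(start + svelt:::cigar_ref_len(cigar)), strand = strand,
    mapq = as.integer(mapq), cigar = cigar,
    is_supplementary = is_supplementary,
    haplotype = as.integer(haplotype), phase_set = as.integer(phase_set),
    sample = sample, seq = seq, sa_tag = sa_tag
  )
}

# One putative-breakpoint row.
breakpoint_row <- function(kind = "split", notation = "+-",
                           contig_a = "chr1", pos_a = 1000L, strand_a = "+",
                           contig_b = "chr1", pos_b = 2000L, strand_b = "-",
                           sv_length = 1000, span = sv_length,
                           inserted_sequence = NA_character_,
                           read_name = "r1", sample = "tumor",
                           haplotype = NA_integer_,
                           phase_set = NA_integer_, mapq = 60) {
  tibble::tibble(
    kind = kind, notation = notation, contig_a = contig_a,
    pos_a = as.integer(pos_a), strand_a = strand_a, contig_b = contig_b,
    pos_b = as.integer(pos_b), strand_b = strand_b,
    sv_length = as.double(sv_length), span = as.double(span),
    inserted_sequence = inserted_sequence, read_name = read_name,
    sample = sample, haplotype = as.integer(haplotype),
    phase_set = as.integer(phase_set), mapq = as.double(mapq)
  )
}

# A classifier stub that predicts a fixed somatic probability per row,
# letting filter-precedence and conformal mechanics be tested in isolation.
constant_model <- function(probs) {
  structure(
    list(model = structure(list(probs = probs), class = "constant_prob"),
         feature_names = sv_feature_names()),
    class = "sv_classifier"
  )
}

predict.constant_prob <- function(object, data, ...) {
  p <- rep_len(object$probs, nrow(data))
  list(predictions = cbind(noise = 1 - p, somatic = p))
}
registerS3method("predict", "constant_prob", predict.constant_prob)

# Brute-force connected components of the "within window" graph; the
# independent oracle for chained clustering.
components_within_window <- function(pos, window) {
  n <- length(pos)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      near <- which(abs(pos - pos[i]) <= window)
      target <- min(comp[near])
      if (any(comp[near] != target)) {
        comp[near] <- target
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# Exhaustive R-side scan of the maximal circular-arc statistic; the oracle
# for the CBS split decision on short series.
max_arc_stat_oracle <- function(x) {
  n <- length(x)
  s2 <- stats::var(x)
  best <- list(stat = 0, i = 0L, j = 0L)
  if (s2 <= 0) return(best)
  for (i in 0:(n - 1)) {
    for (j in (i + 1):n) {
      k <- j - i
      if (k == n) next
      arc <- x[(i + 1):j]
      rest <- x[-((i + 1):j)]
      t <- abs(mean(arc) - mean(rest)) / sqrt(s2 * (1 / k + 1 / (n - k)))
      if (t > best$stat) best <- list(stat = t, i = i, j = j)
    }
  }
  best
}
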