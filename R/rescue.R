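# Copy-number rescue of breakpoints the classifier missed, and germline-panel
# filtering for tumor-only mode.

#' Rescue non-PASS breakpoints at copy-number changepoints
#'
#' A breakpoint that did not pass classification is rescued (set to `PASS`,
#' `rescued = TRUE`, `CLASS = somatic`) when it lies within `distance` bp of
#' a somatic copy-number changepoint, has at least three supporting tumor
#' reads, no supporting reads in the matched normal, and fewer than three
#' normal reads supporting a breakpoint of any type at the same location.
#'
#' @param classified Cluster tibble from [classify_and_filter()].
#' @param changepoints Tibble with `contig`, `pos` (0-based changepoint
#'   positions).
#' @param distance Maximum distance in bp (default 50).
#' @param support_min Minimum tumor support (default 3).
#' @param normal_cluster_max Maximum clustered normal reads (default 3,
#'   exclusive).
#' @return `classified` with updated `filter`, `rescued`, `class_label`.
#' @export
rescue_by_changepoints <- function(classified, changepoints, distance = 50,
                                   support_min = 3, normal_cluster_max = 3) {
  if (nrow(classified) == 0L || is.null(changepoints) ||
      nrow(changepoints) == 0L) {
    return(classified)
  }
  near_cp <- vapply(seq_len(nrow(classified)), function(i) {
    cl <- classified[i, ]
    hit <- changepoints$contig == cl$contig_a &
      abs(changepoints$pos - cl$pos_a) <= distance
    if (!is.na(cl$contig_b)) {
      hit <- hit | (changepoints$contig == cl$contig_b &
                      abs(changepoints$pos - cl$pos_b) <= distance)
    }
    any(hit)
  }, logical(1))
  qualifies <- classified$filter != "PASS" & near_cp &
    classified$tumor_support >= support_min &
    classified$normal_support == 0 &
    classified$normal_any_cluster_reads < normal_cluster_max
  classified |>
    mutate(
      rescued = .data$rescued | qualifies,
      filter = ifelse(qualifies, "PASS", .data$filter),
      class_label = ifelse(qualifies, "somatic", .data$class_label)
    )
}

#' Remove likely germline SVs in tumor-only mode using panels
#'
#' Clusters with any breakend within `buffer` bp of a panel breakend are
#' reclassified as germline and removed from the somatic output. Population
#' panel entries count only when their population allele fraction exceeds
#' `af_threshold`; panel-of-normals entries always count. Removed clusters
#' are retained in the `"germline"` attribute.
#'
#' @param clusters Cluster tibble.
#' @param population_svs Optional tibble of population-panel breakends
#'   (`contig`, `pos`, optional `af`).
#' @param pon_svs Optional tibble of panel-of-normals breakends (`contig`,
#'   `pos`).
#' @param buffer Matching window in bp (default 100).
#' @param af_threshold Population AF gate (default 0.10, exclusive).
#' @return Filtered cluster tibble with attribute `"germline"`.
#' @export
filter_germline_panels <- function(clusters, population_svs = NULL,
                                   pon_svs = NULL, buffer = 100,
                                   af_threshold = 0.10) {
  panel <- list()
  if (!is.null(population_svs) && nrow(population_svs) > 0L) {
    pop <- population_svs
    if ("af" %in% names(pop)) pop <- filter(pop, .data$af > af_threshold)
    panel[[length(panel) + 1L]] <- select(pop, "contig", "pos")
  }
  if (!is.null(pon_svs) && nrow(pon_svs) > 0L) {
    panel[[length(panel) + 1L]] <- select(pon_svs, "contig", "pos")
  }
  if (length(panel) == 0L) {
    attr(clusters, "germline") <- clusters[0, ]
    return(clusters)
  }
  panel <- list_rbind(panel)
  is_germ <- vapply(seq_len(nrow(clusters)), function(i) {
    cl <- clusters[i, ]
    hit <- panel$contig == cl$contig_a & abs(panel$pos - cl$pos_a) <= buffer
    if (!is.na(cl$contig_b)) {
      hit <- hit | (panel$contig == cl$contig_b &
                      abs(panel$pos - cl$pos_b) <= buffer)
    }
    any(hit)
  }, logical(1))
  out <- clusters[!is_germ, ]
  attr(out, "germline") <- clusters[is_germ, ]
  out
}
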