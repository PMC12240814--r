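# ggplot2 views of the main result types.

#' Plot a copy-number profile
#'
#' Bin-level log2 ratios with fitted segment means, faceted by contig.
#'
#' @param bins Normalized bin tibble (with `log2r`).
#' @param segments Optional segment tibble overlaid as horizontal bars.
#' @return A ggplot object.
#' @export
plot_copy_number <- function(bins, segments = NULL) {
  p <- ggplot2::ggplot(bins, ggplot2::aes(
    x = (.data$start + .data$end) / 2e6, y = .data$log2r)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5, colour = "grey40") +
    ggplot2::facet_grid(. ~ contig, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(log[2] ~ ratio)) +
    ggplot2::theme_bw()
  if (!is.null(segments)) {
    p <- p + ggplot2::geom_segment(
      data = segments,
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   y = .data$mean_log2r, yend = .data$mean_log2r),
      colour = "red", linewidth = 1
    )
  }
  p
}

#' Plot B-allele frequencies along the genome
#'
#' @param baf BAF observation tibble.
#' @return A ggplot object.
#' @export
plot_baf <- function(baf) {
  ggplot2::ggplot(baf, ggplot2::aes(x = .data$position / 1e6,
                                    y = .data$baf)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5, colour = "steelblue") +
    ggplot2::facet_grid(. ~ contig, scales = "free_x", space = "free_x") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "position (Mb)", y = "BAF") +
    ggplot2::theme_bw()
}

#' Plot the purity-ploidy fitness grid
#'
#' @param object A `purity_ploidy_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot purity_ploidy_fit
#' @export
autoplot.purity_ploidy_fit <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$ploidy,
                                            y = .data$purity,
                                            fill = .data$fitness)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = tibble(ploidy = object$ploidy,
                                      purity = object$purity),
                        ggplot2::aes(fill = NULL), colour = "red",
                        shape = 4, size = 3) +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = "ploidy", y = "purity",
                  fill = object$metric) +
    ggplot2::theme_bw()
}

#' Plot SV calls along the genome
#'
#' One lollipop per breakend, colored by notation class, shaped by filter.
#'
#' @param object An `sv_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sv_run
#' @export
autoplot.sv_run <- function(object, ...) {
  be <- clusters_to_breakends(object$calls) |>
    left_join(select(object$calls, "cluster_id", "filter", "notation"),
              by = "cluster_id")
  ggplot2::ggplot(be, ggplot2::aes(x = .data$pos / 1e6, y = .data$notation,
                                   colour = .data$notation,
                                   shape = .data$filter)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_grid(. ~ contig, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = NULL) +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
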