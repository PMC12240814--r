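# Ploidy grid search and allele-specific copy number.

#' Absolute copy number from a log2 ratio
#'
#' `CN = ploidy + (2^log2R - 1) * (ploidy + 2/purity - 2)`. At `log2R = 0`
#' the copy number equals the ploidy for any purity.
#'
#' @param log2r Log2 copy-number ratio(s).
#' @param purity Tumor purity in (0, 1].
#' @param ploidy Tumor ploidy.
#' @return Absolute copy number (real-valued).
#' @export
absolute_copy_number <- function(log2r, purity, ploidy) {
  ploidy + (2^log2r - 1) * (ploidy + 2 / purity - 2)
}

#' Grid search for the best-fitting purity and ploidy
#'
#' Scans purity in `purity_hat +- purity_halfwidth` (step 0.01, clipped to
#' (0, 1]) and ploidy in `[ploidy_min, ploidy_max]` (step 0.01). Each
#' combination is scored by the segment-size-weighted deviation (RMSD or MAD)
#' between the inferred absolute copy numbers and their nearest integers, and
#' must pass three plausibility gates: the genome fraction fitted to copy
#' number zero is < 0.1, the fraction of the genome fitted close to an
#' integer (|CN - round(CN)| < 0.25) is > 0.5, and the step between the two
#' most frequent copy-number states is < 2. The accepted combination with the
#' lowest deviation wins; ties break to lower ploidy, then purity nearest
#' `purity_hat`.
#'
#' @param segments Segment tibble with `mean_log2r` and `size` columns.
#' @param purity_hat Purity anchor from [estimate_purity()].
#' @param purity_halfwidth Half-width of the purity window (default 0.1).
#' @param purity_step,ploidy_step Grid steps (default 0.01).
#' @param ploidy_min,ploidy_max Ploidy range (defaults 1.50, 5.00).
#' @param metric `"rmsd"` (default) or `"mad"`.
#' @param zero_max Maximum genome fraction at CN 0 (default 0.1).
#' @param close_min Minimum genome fraction close to an integer (default
#'   0.5).
#' @param close_threshold Closeness threshold (default 0.25).
#' @param step_max Maximum step between the two most frequent states
#'   (default 2).
#' @return A `purity_ploidy_fit` object; the full grid is in `$grid`.
#' @export
grid_search_ploidy <- function(segments, purity_hat, purity_halfwidth = 0.1,
                               purity_step = 0.01, ploidy_min = 1.50,
                               ploidy_max = 5.00, ploidy_step = 0.01,
                               metric = c("rmsd", "mad"), zero_max = 0.1,
                               close_min = 0.5, close_threshold = 0.25,
                               step_max = 2) {
  metric <- match.arg(metric)
  assert_columns(segments, c("mean_log2r", "size"), "segment table")
  purities <- round(seq(purity_hat - purity_halfwidth,
                        purity_hat + purity_halfwidth, by = purity_step), 10)
  purities <- purities[purities > 0 & purities <= 1]
  ploidies <- round(seq(ploidy_min, ploidy_max, by = ploidy_step), 10)
  w <- segments$size / sum(segments$size)
  r <- 2^segments$mean_log2r

  eval_point <- function(purity, ploidy) {
    cn <- ploidy + (r - 1) * (ploidy + 2 / purity - 2)
    dev <- cn - round(cn)
    fitness <- if (metric == "rmsd") sqrt(sum(w * dev^2)) else sum(w * abs(dev))
    states <- round(cn)
    prop_zero <- sum(w[states <= 0])
    prop_close <- sum(w[abs(dev) < close_threshold])
    freq <- sort(tapply(w, states, sum), decreasing = TRUE)
    step <- if (length(freq) >= 2) {
      abs(as.numeric(names(freq)[1]) - as.numeric(names(freq)[2]))
    } else 0
    c(fitness = fitness, prop_zero = prop_zero, prop_close = prop_close,
      step = step)
  }

  grid <- tidyr::expand_grid(purity = purities, ploidy = ploidies)
  vals <- pmap(grid, function(purity, ploidy) eval_point(purity, ploidy))
  grid <- bind_cols(grid, as_tibble(do.call(rbind, vals))) |>
    mutate(
      prop_zero_ok = .data$prop_zero < zero_max,
      prop_integer_ok = .data$prop_close > close_min,
      step_size_ok = .data$step < step_max,
      accepted = .data$prop_zero_ok & .data$prop_integer_ok &
        .data$step_size_ok
    )
  ok <- filter(grid, .data$accepted)
  if (nrow(ok) == 0L) {
    abort(paste0("no purity-ploidy combination passed the plausibility ",
                 "gates; consider supplying purity/ploidy manually"))
  }
  # The fitness surface is degenerate along whole-lattice shifts: (purity',
  # ploidy +- 1) with 2/purity' = 2/purity -+ 1 maps every segment to the
  # neighboring integer and fits exactly as well. Among grid points whose
  # fitness is within a noise margin of the minimum, the combination whose
  # purity is nearest the BAF-derived estimate is therefore preferred; exact
  # remaining ties break to lower ploidy.
  fmin <- min(ok$fitness)
  margin <- 0.05 * fmin + 0.003
  best <- ok |>
    filter(.data$fitness <= fmin + margin) |>
    arrange(abs(.data$purity - purity_hat), .data$ploidy, .data$fitness) |>
    dplyr::slice(1)
  structure(
    list(purity = best$purity, ploidy = best$ploidy,
         fitness = best$fitness, metric = metric, purity_hat = purity_hat,
         flags = c(prop_zero_ok = best$prop_zero_ok,
                   prop_integer_ok = best$prop_integer_ok,
                   step_size_ok = best$step_size_ok),
         accepted = TRUE, grid = grid),
    class = "purity_ploidy_fit"
  )
}

#' @export
print.purity_ploidy_fit <- function(x, ...) {
  cat("<purity_ploidy_fit> purity =", x$purity, " ploidy =", x$ploidy,
      sprintf(" (%s = %.4g)\n", x$metric, x$fitness))
  invisible(x)
}

#' @export
glance.purity_ploidy_fit <- function(x, ...) {
  tibble(purity = x$purity, ploidy = x$ploidy, fitness = x$fitness,
         metric = x$metric, purity_hat = x$purity_hat,
         accepted = x$accepted)
}

#' @export
tidy.purity_ploidy_fit <- function(x, ...) {
  x$grid
}

#' Assign allele-specific (minor) copy number to segments
#'
#' Inverts the BAF model at the fitted purity: with `b` the median mirrored
#' BAF of a segment (values above 0.5 folded to 1 - b, removing phase
#' dependence) and `n_T` the rounded total copy number, the minor copy number
#' is `n_B = (b * (rho * n_T + 2(1 - rho)) - (1 - rho)) / rho`, rounded and
#' clamped to `[0, floor(n_T / 2)]`.
#'
#' @param segments Segment tibble with `contig`, `start`, `end` and
#'   `absolute_cn` (or `mean_log2r` plus `purity`/`ploidy` via `fit`).
#' @param baf BAF observation tibble.
#' @param purity Fitted tumor purity.
#' @param min_snps Minimum SNPs per segment to attempt the fit (default 5).
#' @return `segments` with `minor_cn` (integer or NA) and `n_snps` columns.
#' @export
allele_specific_cn <- function(segments, baf, purity, min_snps = 5) {
  assert_columns(segments, c("contig", "start", "end", "absolute_cn"),
                 "segment table")
  out <- segments
  out$minor_cn <- NA_integer_
  out$n_snps <- 0L
  for (i in seq_len(nrow(out))) {
    sel <- baf$contig == out$contig[i] &
      baf$position > out$start[i] & baf$position <= out$end[i]
    out$n_snps[i] <- sum(sel)
    if (sum(sel) < min_snps) next
    b <- stats::median(pmin(baf$baf[sel], 1 - baf$baf[sel]))
    n_t <- max(round(out$absolute_cn[i]), 0)
    n_b <- (b * (purity * n_t + 2 * (1 - purity)) - (1 - purity)) / purity
    out$minor_cn[i] <- as.integer(min(max(round(n_b), 0), floor(n_t / 2)))
  }
  out
}

#' Attach absolute copy numbers to segments
#'
#' @param segments Segment tibble with `mean_log2r`.
#' @param fit A `purity_ploidy_fit` (or supply `purity` and `ploidy`).
#' @param purity,ploidy Optional manual overrides.
#' @return Segments with `absolute_cn`.
#' @export
fit_absolute_cn <- function(segments, fit = NULL, purity = NULL,
                            ploidy = NULL) {
  purity <- purity %||% fit$purity
  ploidy <- ploidy %||% fit$ploidy
  mutate(segments,
         absolute_cn = absolute_copy_number(.data$mean_log2r, purity, ploidy))
}
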