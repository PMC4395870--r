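#' Plot a FRET-index map
#'
#' Raster of the (median-filtered) index for one frame, valid pixels only —
#' the low-FRET (high-tension) regions show up dark.
#'
#' @param object A [fret_pipeline()] result.
#' @param frame Frame to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fret_map <- function(object, frame = 1, ...) {
  px <- tidy(object)
  px <- px[px$frame == frame & px$valid, ]
  ggplot2::ggplot(px, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$f)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "FRET index", limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row") +
    ggplot2::theme_minimal()
}

#' Paired SDR vs non-SDR plot for an embryo cohort
#'
#' One point per embryo and region, with a line joining the two regions of
#' the same embryo — the standard display for an intra-embryo paired
#' comparison.
#'
#' @param embryos Embryo-level tibble ([pool_embryo()] rows).
#' @return A ggplot object.
#' @export
plot_paired_fret <- function(embryos) {
  long <- tidyr::pivot_longer(embryos, c("sdr_mean", "nonsdr_mean"),
                              names_to = "roi", values_to = "fret") |>
    dplyr::mutate(roi = factor(.data$roi, c("sdr_mean", "nonsdr_mean"),
                               c("SDR", "non-SDR")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$roi, y = .data$fret,
                                     group = .data$embryo_id)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(colour = "firebrick", size = 2) +
    ggplot2::labs(x = NULL, y = "pooled FRET index") +
    ggplot2::theme_classic()
}

#' Region fold-change overview
#'
#' Log2 fold change per region, coloured by category call, with the calling
#' thresholds drawn in.
#'
#' @param calls Output of [classify_regions()].
#' @param threshold Fold threshold used for the calls (drawn as dashed
#'   lines).
#' @return A ggplot object.
#' @export
plot_region_folds <- function(calls, threshold = 1.5) {
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$region_type,
                                      y = log2(.data$fold),
                                      colour = .data$category)) +
    ggplot2::geom_jitter(width = 0.25, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = c(-log2(threshold), log2(threshold)),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = NULL, y = "log2 fold change (mut / wt)") +
    ggplot2::theme_classic()
}
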