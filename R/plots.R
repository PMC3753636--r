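#' Plot a distance-bin profile
#'
#' Bar chart of tag-5'-end counts per percent-distance bin, faceted by
#' cell line, with a dashed marker at the bin the TSS is expected to
#' occupy given the region geometry.
#'
#' @param object a `bin_profile` from [accumulate_profile()].
#' @param tss_offset expected TSS distance from the region 5'-end in bp
#'   (NULL to omit the marker).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot bin_profile
#' @export
autoplot.bin_profile <- function(object, tss_offset = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$bin, y = .data$count)) +
    ggplot2::geom_col(width = 1, fill = "steelblue") +
    ggplot2::facet_wrap(~cell_line) +
    ggplot2::labs(x = "% distance bin", y = "distinct 5'-ends") +
    ggplot2::theme_minimal()
  if (!is.null(tss_offset)) {
    expected <- bin_index(tss_offset, attr(object, "region_length"),
                          attr(object, "n_bins"))
    p <- p + ggplot2::geom_vline(xintercept = expected, linetype = "dashed")
  }
  p
}

#' Plot a windowed physical profile
#'
#' One line per stiffness channel (free y scales: rotational and
#' translational constants live in different units) along the sequence.
#'
#' @param object a `windowed_profile` from [window_average()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot windowed_profile
#' @export
autoplot.windowed_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("center", .channels)],
    cols = dplyr::all_of(.channels),
    names_to = "channel", values_to = "stiffness")
  long$channel <- factor(long$channel, levels = .channels)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$center,
                                     y = .data$stiffness)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "window center (bp)", y = "mean stiffness") +
    ggplot2::theme_minimal()
}

#' Plot a genome scan score track
#'
#' Comparative promoter score along the chromosome, one panel per strand,
#' optionally overlaid with planted/annotated TSS positions.
#'
#' @param scores tibble from [scan_genome()].
#' @param truth optional tibble with `tss` positions to mark.
#' @return a ggplot object.
#' @export
plot_score_track <- function(scores, truth = NULL) {
  p <- ggplot2::ggplot(dplyr::filter(scores, .data$label != "no_call"),
                       ggplot2::aes(x = .data$position, y = .data$score)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::facet_grid(strand ~ chrom) +
    ggplot2::labs(x = "position (bp)",
                  y = "score  (d_background - d_promoter)") +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_vline(data = truth,
                                 ggplot2::aes(xintercept = .data$tss),
                                 colour = "firebrick", alpha = 0.5)
  }
  p
}
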