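# ggplot2 views of the result objects.

#' Plot a coverage track
#'
#' Depth against genomic position, one facet per chromosome.
#'
#' @param object A `coverage_track`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coverage_track <- function(object, ...) {
  tb <- as_tibble(object)
  ggplot2::ggplot(tb, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                   y = .data$depth)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "depth (mean per-bp pileup)")
}

#' Plot a peak call
#'
#' The FDR calibration curve: ChIP and mean background region counts
#' against the candidate height cutoff (log counts), with the chosen
#' cutoff marked.
#'
#' @param object A `peak_call` from [call_peaks()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.peak_call <- function(object, ...) {
  tab <- object$calibration$table
  long <- tidyr::pivot_longer(tab, c("chip_count", "background_count"),
                              names_to = "channel", values_to = "n_regions")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$height, y = .data$n_regions,
                                     colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$calibration$height_cutoff,
                        linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "height cutoff (depth)", y = "regions called",
                  colour = NULL,
                  title = sprintf("%s mode, target FDR %g",
                                  object$config$mode, object$config$fdr))
}

#' Repeat-fraction decile histogram
#'
#' @param x A `repeat_fraction` from [repeat_fraction_histogram()].
#' @return A ggplot of peak counts per percent-repetitive decile.
#' @export
plot_repeat_fraction <- function(x) {
  stopifnot(inherits(x, "repeat_fraction"))
  ggplot2::ggplot(x$histogram, ggplot2::aes(x = .data$decile, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "% of peak covered by repeats", y = "peaks")
}

#' Finger-domain association plot
#'
#' Percent of genes covered by a peak against the number of tandemly
#' repeated finger domains.
#'
#' @param assoc Output of [finger_domain_association()].
#' @return A ggplot.
#' @export
plot_finger_association <- function(assoc) {
  ggplot2::ggplot(assoc, ggplot2::aes(x = .data$n_fingers, y = .data$percent)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "tandemly repeated finger domains",
                  y = "% of genes covered by a peak")
}
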