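#' Plot a sliding-window G+C profile
#'
#' Line plot of window G+C along the sequence, with an optional horizontal
#' reference at the background mean and a shaded band at +/- 2 standard
#' deviations — the visual check behind composition-anomaly calls.
#'
#' @param profile A [gc_windows()] tibble.
#' @param region_gc Optional G+C value of a focal region, drawn as a dashed
#'   line.
#' @return A ggplot object.
#' @export
plot_gc_profile <- function(profile, region_gc = NULL) {
  mu <- mean(profile$gc, na.rm = TRUE)
  sdev <- sd(profile$gc, na.rm = TRUE)
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$start, y = .data$gc)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = mu - 2 * sdev, ymax = mu + 2 * sdev,
                      alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_hline(yintercept = mu, colour = "steelblue") +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "window start (bp)", y = "G+C fraction") +
    ggplot2::theme_minimal()
  if (!is.null(region_gc)) {
    p <- p + ggplot2::geom_hline(yintercept = region_gc, linetype = "dashed",
                                 colour = "firebrick")
  }
  p
}

#' @export
autoplot.chs_gc_profile <- function(object, ...) plot_gc_profile(object, ...)

#' Plot bootstrap support distribution of a tree
#'
#' Histogram of internal-edge supports with the conventional 60% threshold
#' marked; a quick view of how well resolved an inference is.
#'
#' @param boot A [bootstrap_support()] result.
#' @param support_min Threshold line.
#' @return A ggplot object.
#' @export
plot_support_profile <- function(boot, support_min = 60) {
  ggplot2::ggplot(boot$supports, ggplot2::aes(x = .data$support)) +
    ggplot2::geom_histogram(binwidth = 5, boundary = 0, fill = "grey40") +
    ggplot2::geom_vline(xintercept = support_min, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "bootstrap support (%)", y = "internal edges") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.chs_boot_tree <- function(object, ...) plot_support_profile(object, ...)

#' Plot combined horizontal-transfer evidence
#'
#' Tile map of the three evidence lines per candidate, coloured by verdict.
#'
#' @param calls A [combine_evidence()] result.
#' @return A ggplot object.
#' @export
plot_hgt_evidence <- function(calls) {
  long <- calls |>
    select("seq_id", "verdict", "incongruent", "gc_flag", "synteny") |>
    tidyr::pivot_longer(c("incongruent", "gc_flag", "synteny"),
                        names_to = "evidence", values_to = "present")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$evidence, y = .data$seq_id,
                                     alpha = .data$present,
                                     fill = .data$verdict)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.15)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.chs_hgt_calls <- function(object, ...) plot_hgt_evidence(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
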