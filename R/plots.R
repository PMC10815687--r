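#' Plot a tag-SNV LD scan
#'
#' r-squared against position, with the tag highlighted and the divergence
#' threshold drawn; haplotype-divergent SNVs cluster on the threshold line.
#'
#' @param object An `h2_ld_scan` from [r2_scan()].
#' @param r2_min Divergence threshold to draw (default 0.99).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.h2_ld_scan <- function(object, r2_min = 0.99, ...) {
  df <- as_tibble(object) |> filter(!.data$excluded)
  tag_pos <- attr(object, "tag_pos")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos / 1e6, y = .data$r_squared)) +
    ggplot2::geom_hline(yintercept = r2_min, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::geom_vline(xintercept = tag_pos / 1e6, colour = "firebrick",
                        linetype = "dotted") +
    ggplot2::labs(x = "position (Mb)", y = expression(r^2),
                  title = sprintf("LD with tag SNV %s", attr(object, "tag_id"))) +
    ggplot2::theme_minimal()
}

#' Forest plot of stratified association results
#'
#' Odds ratios with confidence intervals per stratum, faceted by genetic
#' model, on a log scale with the null at 1.
#'
#' @param object An `h2_assoc` tibble from [stratified_association()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.h2_assoc <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$odds_ratio, y = .data$stratum)) +
    ggplot2::geom_vline(xintercept = 1, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~model, ncol = 1) +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.h2_ld_scan
#' @export
plot_r2_scan <- function(object, r2_min = 0.99, ...) {
  autoplot.h2_ld_scan(object, r2_min = r2_min, ...)
}

#' @rdname autoplot.h2_assoc
#' @export
plot_association_forest <- function(object, ...) {
  autoplot.h2_assoc(object, ...)
}
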