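#' Plot topology-stability curves
#'
#' Mean repeats-until-match and mean bootstrap support against the number of
#' subsampled genes N.
#'
#' @param jk A `jackknife_table` from [gene_jackknife()].
#' @return A ggplot object.
#' @export
plot_jackknife <- function(jk) {
  sm <- jackknife_summary(jk)
  long <- tidyr::pivot_longer(sm, c("mean_repeats", "mean_support"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$N, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y",
                        labeller = ggplot2::as_labeller(c(
                          mean_repeats = "mean repeats until match",
                          mean_support = "mean bootstrap support (%)"))) +
    ggplot2::labs(x = "number of genes (N)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-taxon Ks distributions
#'
#' @param ksd Result of [ks_distribution()].
#' @return A ggplot object.
#' @export
plot_ks_distribution <- function(ksd) {
  h <- ksd$histogram
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = (h$bin_hi - h$bin_lo)[1L] %||% 0.05) +
    ggplot2::facet_wrap(~taxon, scales = "free_y") +
    ggplot2::labs(x = "Ks (synonymous substitutions per synonymous site)",
                  y = "paralog pairs") +
    ggplot2::theme_minimal()
}

#' Plot posterior node-age estimates
#'
#' Posterior means with 95% credible intervals for every internal node of a
#' dated tree.
#'
#' @param dt A `dated_tree` from [strict_clock_date()].
#' @return A ggplot object.
#' @export
plot_node_ages <- function(dt) {
  est <- dt$estimates[dt$estimates$parameter != "rate", ]
  est$label <- vapply(dt$node_map[est$parameter], function(x)
    paste(x[c(1, length(x))], collapse = ".."), character(1))
  ggplot2::ggplot(est, ggplot2::aes(x = .data$mean, y = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lwr, xmax = .data$upr),
                            height = 0.2) +
    ggplot2::labs(x = "age (Ma)", y = "clade") +
    ggplot2::theme_minimal()
}
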