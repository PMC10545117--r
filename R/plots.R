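# ggplot2 views of the main result types.

#' Plot a population metric against an expansion covariate
#'
#' Scatter of one metric-table column against a covariate with the OLS line,
#' the view behind the distance-correlation panels.
#'
#' @param table metric table from [assemble_metric_table()].
#' @param metric,covariate column names (strings).
#' @return A ggplot object.
#' @export
plot_distance_trend <- function(table, metric, covariate = "distance_south") {
  ggplot2::ggplot(table, ggplot2::aes(.data[[covariate]], .data[[metric]])) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(x = covariate, y = metric) +
    ggplot2::theme_minimal()
}

#' Plot per-population load means with SD bars
#'
#' @param load_summary tibble from [population_load_summary()].
#' @return A ggplot object faceted by effect class and load type.
#' @export
plot_load_by_population <- function(load_summary) {
  ggplot2::ggplot(load_summary,
                  ggplot2::aes(.data$population, .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.3
    ) +
    ggplot2::facet_grid(load_type ~ effect, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot LD decay curves
#' @param curve tibble from [ld_decay()].
#' @return A ggplot object.
#' @export
plot_ld_decay <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(.data$dist_mid, .data$mean_r2,
                                      colour = .data$population)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "distance (bp)", y = expression(mean ~ r^2)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Histogram of the diploid resampling null with the observed value
#' @param object a `surf_resample` from [resample_diploid_load()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.surf_resample <- function(object, ...) {
  ggplot2::ggplot(tibble(ratio = object$null), ggplot2::aes(.data$ratio)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = expression(pi[N] / pi[S]), y = "resampled sets") +
    ggplot2::theme_minimal()
}

#' Barplot of an unfolded SFS pair
#' @param object a `surf_sfs`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.surf_sfs <- function(object, ...) {
  df <- tibble(
    class = rep(seq_len(object$n - 1), 2),
    count = c(object$syn_sfs, object$nonsyn_sfs),
    type = rep(c("synonymous", "nonsynonymous"), each = object$n - 1)
  )
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$class), .data$count,
                                   fill = .data$type)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "derived allele count", y = "sites") +
    ggplot2::theme_minimal()
}

#' Fitted DFE: discretized mass per selection-strength bin
#' @param object a `surf_dfe_fit`.
#' @param breaks bin edges on |S| for the deleterious mass.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.surf_dfe_fit <- function(object, breaks = c(0, 1, 10, 100, Inf),
                                  ...) {
  p <- object$params
  scale <- abs(p$mean_Sd) / p$shape
  lo <- head(breaks, -1); hi <- tail(breaks, -1)
  mass <- (1 - p$p_b) *
    (pgamma(hi, p$shape, scale = scale) - pgamma(lo, p$shape, scale = scale))
  df <- tibble(
    bin = factor(sprintf("%g-%g", lo, hi), levels = sprintf("%g-%g", lo, hi)),
    mass = mass
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$bin, .data$mass)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "|S| = 4Ne|s|", y = "DFE mass") +
    ggplot2::theme_minimal()
}
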