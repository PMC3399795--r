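#' Crescent-curve plot of a pairwise comparison
#'
#' Per-miRNA log2 ratios plotted in ascending order — the characteristic
#' crescent curve. Positive values are miRNAs expressed higher in the
#' numerator library, negative values lower; the diamond marks the median,
#' whose position shows whether most values are positive or negative.
#'
#' @param object a `crescent_summary`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot crescent_summary
#' @export
autoplot.crescent_summary <- function(object, ...) {
  df <- object$ratios %>% mutate(rank = dplyr::row_number())
  med_rank <- which.min(abs(df$log2_ratio - object$median))[1]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$log2_ratio)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::annotate("point", x = med_rank, y = object$median,
                      shape = 18, size = 4, colour = "red") +
    ggplot2::labs(
      title = object$pair,
      subtitle = sprintf("%.0f%% up / %.0f%% down, median %.3f, chi2 p = %.2g",
                         object$pct_up, object$pct_down, object$median,
                         object$chi2_p),
      x = "miRNA rank", y = "log2 expression ratio") +
    ggplot2::theme_minimal()
}

#' Additivity crescent plot for a hybrid
#'
#' Log2 deviations from the dosage-weighted mid-parent expectation in
#' ascending order, with the additivity band and the median (X) marked.
#'
#' @param object an `additivity_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot additivity_result
#' @export
autoplot.additivity_result <- function(object, ...) {
  df <- object$table %>% mutate(rank = dplyr::row_number())
  med_rank <- which.min(abs(df$log2_deviation - object$median))[1]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank,
                                   y = .data$log2_deviation)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_hline(yintercept = c(-object$band, object$band),
                        linetype = "dotted", colour = "grey30") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::annotate("point", x = med_rank, y = object$median,
                      shape = 4, size = 4, stroke = 1.5, colour = "red") +
    ggplot2::labs(
      title = sprintf("Additivity: %s", object$label),
      subtitle = sprintf("%.0f%% over / %.0f%% under, %.0f%% within band, chi2 p = %.2g",
                         object$pct_over, object$pct_under,
                         100 * object$within_band_fraction, object$chi2_p),
      x = "miRNA rank", y = "log2 (observed / expected)") +
    ggplot2::theme_minimal()
}

#' Read-length distribution plot
#'
#' @param lib a `tag_library` (or a list of them to facet).
#' @param weighted count reads (default) or unique tags per length.
#' @return a ggplot object.
#' @export
plot_length_distribution <- function(lib, weighted = TRUE) {
  libs <- if (inherits(lib, "tag_library")) list(lib) else lib
  df <- bind_rows(lapply(libs, function(l) {
    length_distribution(l, weighted = weighted) %>%
      mutate(library = lib_label(l))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~library, scales = "free_y") +
    ggplot2::labs(x = "read length (nt)",
                  y = if (weighted) "reads" else "unique tags") +
    ggplot2::theme_minimal()
}
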