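#' Tidy a crescent summary
#'
#' One row per miRNA, ratios ascending, with the regulation direction and a
#' flag for changes of more than one log2 unit (the "more than 1-fold"
#' convention on logarithmized ratios).
#'
#' @param x a `crescent_summary`.
#' @param ... unused.
#' @return tibble with columns `mirna`, `log2_ratio`, `direction`,
#'   `gt_onefold`.
#' @method tidy crescent_summary
#' @export
tidy.crescent_summary <- function(x, ...) {
  x$ratios %>%
    mutate(direction = dplyr::case_when(.data$log2_ratio > 0 ~ "up",
                                        .data$log2_ratio < 0 ~ "down",
                                        TRUE ~ "zero"),
           gt_onefold = abs(.data$log2_ratio) > 1)
}

#' @rdname tidy.crescent_summary
#' @return for `glance()`: a one-row tibble of summary statistics.
#' @method glance crescent_summary
#' @export
glance.crescent_summary <- function(x, ...) {
  tibble(pair = x$pair, n = x$n, n_up = x$n_up, n_down = x$n_down,
         n_zero = x$n_zero, pct_up = x$pct_up, pct_down = x$pct_down,
         median = x$median, chi2_stat = x$chi2_stat, chi2_p = x$chi2_p,
         pseudocount = x$pseudocount)
}

#' Tidy an additivity result
#'
#' One row per miRNA with observed and expected proportions, the log2
#' deviation, and whether it falls outside the additivity band.
#'
#' @param x an `additivity_result`.
#' @param ... unused.
#' @return tibble with columns `mirna`, `observed`, `expected`,
#'   `log2_deviation`, `outside_band`, ascending in deviation.
#' @method tidy additivity_result
#' @export
tidy.additivity_result <- function(x, ...) {
  x$table
}

#' @rdname tidy.additivity_result
#' @return for `glance()`: a one-row tibble of summary statistics.
#' @method glance additivity_result
#' @export
glance.additivity_result <- function(x, ...) {
  tibble(hybrid = x$label,
         composition = if (!is.null(x$composition))
           format(x$composition) else NA_character_,
         n = x$n, n_over = x$n_over, n_under = x$n_under,
         n_zero = x$n_zero, pct_over = x$pct_over,
         pct_under = x$pct_under,
         within_band_fraction = x$within_band_fraction,
         median = x$median, chi2_stat = x$chi2_stat, chi2_p = x$chi2_p,
         band = x$band, pseudocount = x$pseudocount)
}
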