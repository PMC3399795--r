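#' Pearson correlation between two expression profiles
#'
#' The correlation of the paired per-miRNA proportions: the covariance of
#' the two samples divided by the product of their standard deviations,
#' computed on the linear proportions (not log ratios).
#'
#' @param a,b `expression_profile` objects over a shared miRNA universe.
#' @return Pearson r (single number in `[-1, 1]`).
#' @export
profile_correlation <- function(a, b) {
  common <- intersect(a$mirna, b$mirna)
  if (length(common) < 3) abort("Need at least 3 shared miRNAs.")
  va <- setNames(a$proportion, a$mirna)[common]
  vb <- setNames(b$proportion, b$mirna)[common]
  if (sd(va) == 0 || sd(vb) == 0) {
    abort("Correlation undefined: zero variance in a profile.",
          class = "polymir_undefined_correlation")
  }
  unname(cor(va, vb))
}

#' Default pseudocount for log-ratio comparisons
#'
#' Half a read in proportion units of the shallower library:
#' `0.5 / min(total miRNA reads)`. Keeps every log ratio finite while
#' shrinking extreme ratios least for deep libraries.
#'
#' @param ... `expression_profile` objects entering the comparison.
#' @return a single pseudocount value.
#' @export
default_pseudocount <- function(...) {
  depths <- vapply(list(...), function(p) {
    d <- total_mirna_reads(p)
    if (is.null(d)) NA_real_ else d
  }, numeric(1))
  depths <- depths[is.finite(depths)]
  if (!length(depths)) return(1e-6)
  0.5 / min(depths)
}

#' Per-miRNA log2 expression ratios between two libraries
#'
#' `log2((a + eps) / (b + eps))` of the proportions, over the shared
#' universe of the two profiles. Antisymmetric under argument swap.
#'
#' @param a numerator profile, `b` denominator profile.
#' @param b see `a`.
#' @param pseudocount `eps`; defaults to [default_pseudocount()] of the
#'   pair. Use 0 only when no proportion is zero.
#' @return a `fold_change_set`: tibble with columns `mirna`, `log2_ratio`,
#'   with attributes `numerator`, `denominator`, `pseudocount`.
#' @export
fold_changes <- function(a, b, pseudocount = NULL) {
  pseudocount <- pseudocount %||% default_pseudocount(a, b)
  if (pseudocount < 0) abort("`pseudocount` must be non-negative.")
  common <- intersect(a$mirna, b$mirna)
  va <- setNames(a$proportion, a$mirna)[common]
  vb <- setNames(b$proportion, b$mirna)[common]
  out <- tibble(mirna = common,
                log2_ratio = unname(log2((va + pseudocount) /
                                         (vb + pseudocount))))
  structure(out,
            numerator = lib_label(a), denominator = lib_label(b),
            pseudocount = pseudocount,
            class = c("fold_change_set", class(out)))
}

#' Fold-change ratios from plain vectors
#'
#' Lower-level companion to [fold_changes()] for callers holding aligned
#' proportion vectors (e.g. columns of [expression_matrix()]).
#'
#' @param num,den named numeric proportion vectors over the same universe.
#' @param pseudocount added to both before the ratio.
#' @param labels length-2 character: numerator and denominator labels.
#' @return a `fold_change_set`.
#' @export
fold_changes_vec <- function(num, den, pseudocount = 0,
                             labels = c("a", "b")) {
  if (pseudocount < 0) abort("`pseudocount` must be non-negative.")
  stopifnot(identical(names(num), names(den)))
  out <- tibble(mirna = names(num),
                log2_ratio = log2((unname(num) + pseudocount) /
                                  (unname(den) + pseudocount)))
  structure(out, numerator = labels[1], denominator = labels[2],
            pseudocount = pseudocount,
            class = c("fold_change_set", class(out)))
}

fc_pair_label <- function(fc) {
  paste0(attr(fc, "numerator"), "/", attr(fc, "denominator"))
}

#' Crescent-curve summary of a pairwise comparison
#'
#' Sorts the per-miRNA log2 ratios ascending (the "crescent curve"),
#' classifies each as up (> 0), down (< 0) or zero, and tests the up/down
#' split against equal proportions with a 1-df chi-square goodness-of-fit
#' test (zeros excluded, no continuity correction). The median is taken
#' over all ratios, zeros included; its sign shows whether most miRNAs are
#' higher or lower in the numerator library.
#'
#' @param fc a `fold_change_set`.
#' @param zero_tol ratios within `zero_tol` of 0 count as unchanged
#'   (numerical guard, not a biological threshold).
#' @return a `crescent_summary` object; see [tidy()] / [glance()] /
#'   [autoplot()] methods.
#' @export
crescent_summary <- function(fc, zero_tol = 1e-12) {
  r <- fc$log2_ratio
  if (length(r) < 1) abort("Need at least one ratio.")
  # |ratio| at or below zero_tol counts as unchanged: guards the up/down
  # classification against floating-point residue in computed ratios
  n_up <- sum(r > zero_tol); n_down <- sum(r < -zero_tol)
  n_zero <- length(r) - n_up - n_down
  test <- updown_chisq(n_up, n_down)
  structure(list(
    pair = fc_pair_label(fc),
    numerator = attr(fc, "numerator"),
    denominator = attr(fc, "denominator"),
    pseudocount = attr(fc, "pseudocount"),
    ratios = arrange(as_tibble(fc)[c("mirna", "log2_ratio")],
                     .data$log2_ratio),
    n = length(r), n_up = n_up, n_down = n_down, n_zero = n_zero,
    pct_up = 100 * n_up / length(r), pct_down = 100 * n_down / length(r),
    median = median(r),
    chi2_stat = test$statistic, chi2_p = test$p_value),
    class = "crescent_summary")
}

#' @export
print.crescent_summary <- function(x, ...) {
  cat(sprintf(paste0("<crescent_summary> %s: %d miRNAs, %.1f%% up / %.1f%% down,",
                     " median %.3f, chi2 = %.2f (p = %.3g)\n"),
              x$pair, x$n, x$pct_up, x$pct_down, x$median,
              x$chi2_stat, x$chi2_p))
  invisible(x)
}

#' Bin fold changes as under-, unchanged or over-expressed
#'
#' Counts linear-scale ratios `2^log2_ratio` falling below 0.5, between
#' 0.5 and 2 (inclusive), or above 2 — the conventional two-fold window
#' within which expression is called unchanged.
#'
#' @param fc a `fold_change_set`.
#' @return tibble with columns `bin` (`"<0.5"`, `"0.5-2"`, `">2"`) and `n`.
#' @export
fold_change_bins <- function(fc) {
  ratio <- 2^fc$log2_ratio
  tibble(bin = factor(c("<0.5", "0.5-2", ">2"),
                      levels = c("<0.5", "0.5-2", ">2")),
         n = c(sum(ratio < 0.5),
               sum(ratio >= 0.5 & ratio <= 2),
               sum(ratio > 2)))
}

#' Directional consistency of regulation across comparisons
#'
#' Among the miRNAs up-regulated in the primary comparison (ratio > 0, or
#' > `cutoff` when one is given), reports the fraction also up-regulated in
#' at least one / in all of the other comparisons, and symmetrically for
#' the down direction. With a cutoff, the consistently regulated miRNA
#' names are listed.
#'
#' @param primary a `fold_change_set`.
#' @param others list of `fold_change_set`s over the primary's universe.
#' @param cutoff log2 threshold (e.g. 1 for "more than 1 fold" on the log2
#'   scale), or `NULL` for any non-zero change.
#' @return tibble with one row per direction: `direction`, `n_primary`,
#'   `frac_any`, `frac_all`, `n_all`, and (list-columns) the consistently
#'   regulated miRNAs when a cutoff is given.
#' @export
consistency_across <- function(primary, others, cutoff = NULL) {
  thr <- cutoff %||% 0
  sel <- function(fc, dir) {
    r <- setNames(fc$log2_ratio, fc$mirna)
    if (dir == "up") names(r)[r > thr] else names(r)[r < -thr]
  }
  row_for <- function(dir) {
    prim <- sel(primary, dir)
    oth <- lapply(others, sel, dir = dir)
    if (length(prim) == 0) {
      return(tibble(direction = dir, n_primary = 0L,
                    frac_any = NA_real_, frac_all = NA_real_, n_all = 0L,
                    mirnas_all = list(character(0))))
    }
    in_any <- vapply(prim, function(m) any(vapply(oth, function(o)
      m %in% o, logical(1))), logical(1))
    in_all <- vapply(prim, function(m) all(vapply(oth, function(o)
      m %in% o, logical(1))), logical(1))
    tibble(direction = dir, n_primary = length(prim),
           frac_any = mean(in_any), frac_all = mean(in_all),
           n_all = sum(in_all),
           mirnas_all = list(if (!is.null(cutoff)) sort(prim[in_all])
                             else character(0)))
  }
  bind_rows(row_for("up"), row_for("down"))
}
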