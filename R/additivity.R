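#' Dosage-weighted mid-parent expected profile
#'
#' The additive expectation for a hybrid: the dosage-weighted mean of the
#' parental expression profiles. For a PA diploid (dosage P:1, A:1) this is
#' (PP+AA)/2; for a PAA triploid (P:1, A:2) it is (PP+2AA)/3. Parental
#' profiles enter as proportions, and a weighted mean of proportion
#' vectors is itself a proportion vector, so no renormalization is needed.
#'
#' @param parents named list mapping each parental genome symbol to its
#'   `expression_profile` (e.g. `list(P = pp_profile, A = aa_profile)`).
#' @param composition a [genome_composition()] of the hybrid.
#' @param universe optional miRNA universe; defaults to the intersection of
#'   the parental universes.
#' @return tibble with columns `mirna` and `expected`.
#' @export
expected_profile <- function(parents, composition, universe = NULL) {
  composition <- genome_composition(composition)
  dosage <- composition$dosage[composition$dosage > 0]
  missing <- setdiff(names(dosage), names(parents))
  if (length(missing)) {
    abort(sprintf("No parental profile for genome(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "polymir_missing_parent")
  }
  universe <- universe %||%
    Reduce(intersect, lapply(parents[names(dosage)], function(p) p$mirna))
  expected <- Reduce(`+`, lapply(names(dosage), function(g) {
    p <- parents[[g]]
    v <- setNames(p$proportion, p$mirna)[universe]
    v[is.na(v)] <- 0
    dosage[[g]] * v
  })) / sum(dosage)
  tibble(mirna = universe, expected = unname(expected))
}

#' Deviation of a hybrid from its additive expectation
#'
#' For each miRNA, `log2((observed + eps) / (expected + eps))`, classified
#' as over- (> 0) or under-expressed (< 0) relative to the mid-parent
#' expectation. Reports the fraction of miRNAs whose deviation lies
#' strictly between `-band` and `band` (markedly non-additive miRNAs fall
#' outside), the median deviation, and a 1-df chi-square goodness-of-fit
#' test of the over/under split against equal proportions (exact zeros
#' excluded).
#'
#' @param observed the hybrid's `expression_profile`.
#' @param expected tibble from [expected_profile()] (or a named numeric
#'   vector of expected proportions).
#' @param band log2 half-width of the "not markedly different" band
#'   (default 1, i.e. within two-fold of expectation).
#' @param pseudocount `eps`; defaults to half a read in the observed
#'   library's proportion units (same policy as [fold_changes()]).
#' @param zero_tol deviations within `zero_tol` of 0 count as exactly
#'   additive (numerical guard).
#' @return an `additivity_result` object; see [tidy()], [glance()],
#'   [autoplot()].
#' @export
additivity_deviation <- function(observed, expected, band = 1,
                                 pseudocount = NULL, zero_tol = 1e-12) {
  if (is.data.frame(expected)) {
    expected <- setNames(expected$expected, expected$mirna)
  }
  if (all(expected == 0)) {
    abort("Expected profile is all zero.",
          class = "polymir_degenerate_expectation")
  }
  pseudocount <- pseudocount %||% default_pseudocount(observed)
  common <- intersect(observed$mirna, names(expected))
  obs <- setNames(observed$proportion, observed$mirna)[common]
  exp_ <- expected[common]
  dev <- log2((obs + pseudocount) / (exp_ + pseudocount))
  n_over <- sum(dev > zero_tol); n_under <- sum(dev < -zero_tol)
  n_zero <- length(dev) - n_over - n_under
  # perfectly additive input: no imbalance evidence, not an error
  test <- if (n_over + n_under == 0) list(statistic = 0, p_value = 1)
          else updown_chisq(n_over, n_under)
  tbl <- tibble(mirna = common, observed = unname(obs),
                expected = unname(exp_), log2_deviation = unname(dev),
                outside_band = abs(dev) >= band) %>%
    arrange(.data$log2_deviation)
  structure(list(
    label = lib_label(observed),
    composition = attr(observed, "composition"),
    table = tbl,
    band = band, pseudocount = pseudocount,
    n = length(dev), n_over = n_over, n_under = n_under, n_zero = n_zero,
    pct_over = 100 * n_over / length(dev),
    pct_under = 100 * n_under / length(dev),
    within_band_fraction = mean(dev > -band & dev < band),
    median = median(dev),
    chi2_stat = test$statistic, chi2_p = test$p_value),
    class = "additivity_result")
}

#' @export
print.additivity_result <- function(x, ...) {
  cat(sprintf(paste0("<additivity_result> %s: %d miRNAs, %.0f%% over / %.0f%% under",
                     " expectation, median %.3f, %.0f%% within band,",
                     " chi2 = %.2f (p = %.3g)\n"),
              x$label, x$n, x$pct_over, x$pct_under, x$median,
              100 * x$within_band_fraction, x$chi2_stat, x$chi2_p))
  invisible(x)
}

#' Combined additivity summary across hybrids
#'
#' @param results list of `additivity_result` objects.
#' @return tibble with one row per hybrid (the [glance()] rows bound
#'   together).
#' @export
additivity_report <- function(results) {
  if (length(results) < 1) abort("Need at least one additivity result.")
  bind_rows(lapply(results, glance))
}
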