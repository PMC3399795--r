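#' Common and exclusive unique sequences between two libraries
#'
#' Exact set intersection on unique tag sequences (read counts play no
#' role): how many tags two libraries share, how many are exclusive to
#' each, and the shared percentage from each library's point of view. The
#' single "percent common" reported per pair is the mean of the two
#' directional percentages.
#'
#' @param a,b `tag_library` objects.
#' @return one-row tibble with columns `library_a`, `library_b`,
#'   `shared_count`, `exclusive_a`, `exclusive_b`, `shared_pct_a`,
#'   `shared_pct_b`, `shared_pct_mean`.
#' @export
pairwise_shared <- function(a, b) {
  for (lib in list(a, b)) {
    if (nrow(lib) == 0) {
      abort(sprintf("Library '%s' is empty.", lib_label(lib)),
            class = "polymir_empty_library")
    }
  }
  shared <- sum(a$seq %in% b$seq)
  na <- nrow(a); nb <- nrow(b)
  tibble(library_a = lib_label(a), library_b = lib_label(b),
         shared_count = shared,
         exclusive_a = na - shared, exclusive_b = nb - shared,
         shared_pct_a = 100 * shared / na,
         shared_pct_b = 100 * shared / nb,
         shared_pct_mean = 50 * shared / na + 50 * shared / nb)
}

#' All pairwise shared-sequence comparisons
#'
#' Runs [pairwise_shared()] over every unordered pair of libraries and
#' attaches a per-library summary (mean and standard deviation of the
#' library's directional shared percentage across its comparisons),
#' retrievable with [shared_library_summary()].
#'
#' @param libs list of at least two `tag_library` objects.
#' @return tibble with one row per unordered pair (columns as
#'   [pairwise_shared()]).
#' @export
shared_matrix <- function(libs) {
  if (length(libs) < 2) abort("Need at least two libraries.")
  labels <- vapply(libs, lib_label, character(1))
  if (anyDuplicated(labels)) abort("Library labels must be unique.")
  pairs <- utils::combn(length(libs), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    pairwise_shared(libs[[pairs[1, j]]], libs[[pairs[2, j]]])
  })
  out <- bind_rows(rows)
  per_lib <- lapply(labels, function(lbl) {
    pct <- c(out$shared_pct_a[out$library_a == lbl],
             out$shared_pct_b[out$library_b == lbl])
    tibble(library = lbl, n_comparisons = length(pct),
           mean_shared_pct = mean(pct),
           sd_shared_pct = if (length(pct) > 1) sd(pct) else NA_real_)
  })
  attr(out, "library_summary") <- bind_rows(per_lib)
  out
}

#' @rdname shared_matrix
#' @param shared output of [shared_matrix()].
#' @return for `shared_library_summary()`: tibble with columns `library`,
#'   `n_comparisons`, `mean_shared_pct`, `sd_shared_pct`.
#' @export
shared_library_summary <- function(shared) {
  s <- attr(shared, "library_summary")
  if (is.null(s)) abort("No library summary attached; run shared_matrix().")
  s
}
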