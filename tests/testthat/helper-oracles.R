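# Independent brute-force oracles, kept deliberately naive: plain loops and
# textbook formulas, no shared code with the package internals they check.

oracle_shared <- function(a_seqs, b_seqs) {
  shared <- 0
  for (s in a_seqs) if (s %in% b_seqs) shared <- shared + 1
  list(shared = shared,
       exclusive_a = length(a_seqs) - shared,
       exclusive_b = length(b_seqs) - shared,
       pct_a = 100 * shared / length(a_seqs),
       pct_b = 100 * shared / length(b_seqs))
}

oracle_crescent <- function(ratios) {
  n_up <- 0; n_down <- 0; n_zero <- 0
  for (r in ratios) {
    if (r > 0) n_up <- n_up + 1
    else if (r < 0) n_down <- n_down + 1
    else n_zero <- n_zero + 1
  }
  e <- (n_up + n_down) / 2
  stat <- (n_up - e)^2 / e + (n_down - e)^2 / e
  list(n_up = n_up, n_down = n_down, n_zero = n_zero,
       median = median(ratios), chi2_stat = stat,
       chi2_p = pchisq(stat, df = 1, lower.tail = FALSE))
}

oracle_bins <- function(log2_ratios) {
  lo <- 0; mid <- 0; hi <- 0
  for (r in 2^log2_ratios) {
    if (r < 0.5) lo <- lo + 1
    else if (r > 2) hi <- hi + 1
    else mid <- mid + 1
  }
  c(lo, mid, hi)
}

# Expected category per tag: pool the categories of all features sharing at
# least one base with any of the tag's hits (strand must match for miRNA),
# then take the highest-priority category.
oracle_annotate <- function(hits, features) {
  priority <- c("rRNA", "tRNA", "snRNA", "snoRNA", "mRNA",
                "miRNA", "repeat", "exon", "intron")
  res <- list()
  for (tag in unique(hits$seq)) {
    cats <- character(0)
    h_rows <- which(hits$seq == tag)
    for (i in h_rows) {
      for (j in seq_len(nrow(features))) {
        if (hits$seq_id[i] != features$seq_id[j]) next
        overlaps <- hits$start[i] <= features$end[j] &&
          hits$end[i] >= features$start[j]
        if (!overlaps) next
        if (features$category[j] == "miRNA" &&
            hits$strand[i] != features$strand[j]) next
        cats <- c(cats, features$category[j])
      }
    }
    res[[tag]] <- if (length(cats) == 0) "unannotated"
                  else priority[min(match(cats, priority))]
  }
  res
}

# Tiny tag library straight from sequences (counts default to 1 each).
make_library <- function(seqs, counts = NULL, label = "lib",
                         composition = NULL) {
  counts <- counts %||% rep(1L, length(seqs))
  tag_library(tibble::tibble(seq = seqs, count = counts), label,
              composition)
}

# Valid 22-nt reads for filter fixtures.
random_reads <- function(n, length = 22) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = "")
  }, character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
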