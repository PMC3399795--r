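# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
# `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    abort("`seed` must be a single finite number or NULL.")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive a child seed (kept below 2^31) from a parent seed.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1009 + 97 * k) %% 2147483647L)
}

assert_positive_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 1 ||
      x != floor(x)) {
    abort(sprintf("`%s` must be a positive integer, got %s.", name,
                  paste(format(x), collapse = ", ")))
  }
  invisible(as.integer(x))
}

# Goodness-of-fit chi-square of an up/down (or over/under) split against an
# equal-proportions expectation, 1 df, no continuity correction.
updown_chisq <- function(n_up, n_down) {
  n <- n_up + n_down
  if (n == 0) {
    abort("Degenerate test: no non-zero ratios to classify.",
          class = "polymir_degenerate_test")
  }
  ht <- suppressWarnings(chisq.test(c(n_up, n_down), p = c(0.5, 0.5),
                                    correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}

# Write a tibble as a plain TSV (no quoting, no row names) — the on-disk
# format used throughout the pipeline.
write_tsv_plain <- function(x, path) {
  df <- as.data.frame(x)
  list_cols <- vapply(df, is.list, logical(1))
  for (j in which(list_cols)) {
    df[[j]] <- vapply(df[[j]], function(v) paste(v, collapse = ","),
                      character(1))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

random_dna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = "")
  }, character(1))
}
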