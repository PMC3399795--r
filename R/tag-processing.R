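#' Read a FASTQ file into a tibble
#'
#' Reads 4-line-per-record FASTQ (plain or gzipped). Sequences are kept as
#' written; use [filter_reads()] for normalization and quality control.
#'
#' @param path FASTQ file path (`.gz` handled transparently).
#' @return tibble with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0) return(tibble(id = character(),
                                        seq = character(),
                                        qual = character()))
  if (length(lines) %% 4 != 0) {
    abort(sprintf("Malformed FASTQ: truncated record %d.",
                  length(lines) %/% 4 + 1),
          class = "polymir_format_error")
  }
  idx <- seq(1, length(lines), by = 4)
  bad_head <- which(substr(lines[idx], 1, 1) != "@")
  bad_sep <- which(substr(lines[idx + 2], 1, 1) != "+")
  bad_len <- which(nchar(lines[idx + 1]) != nchar(lines[idx + 3]))
  bad <- c(bad_head, bad_sep, bad_len)
  if (length(bad)) {
    abort(sprintf("Malformed FASTQ record %d in %s.", min(bad), path),
          class = "polymir_format_error")
  }
  tibble(id = sub("^@", "", lines[idx]),
         seq = lines[idx + 1],
         qual = lines[idx + 3])
}

# Mean Phred+33 quality per read; NA_real_ for empty strings.
mean_phred <- function(qual) {
  vapply(qual, function(q) {
    if (!nchar(q)) return(NA_real_)
    mean(utf8ToInt(q) - 33L)
  }, numeric(1), USE.NAMES = FALSE)
}

# Position at which to cut the 3' adapter, or 0 for no trim. The full
# adapter is searched anywhere in the read; failing that, the longest
# adapter prefix (>= min_overlap) matching the read's 3' end is trimmed.
adapter_cut <- function(seqs, adapter, min_overlap = 6) {
  if (is.null(adapter) || !nzchar(adapter)) return(integer(length(seqs)))
  hit <- regexpr(adapter, seqs, fixed = TRUE)
  cut <- ifelse(hit > 0, as.integer(hit), 0L)
  need <- which(cut == 0L)
  alen <- nchar(adapter)
  for (i in need) {
    L <- nchar(seqs[i])
    for (k in seq(min(alen - 1, L), min_overlap)) {
      if (substr(seqs[i], L - k + 1, L) == substr(adapter, 1, k)) {
        cut[i] <- L - k + 1L
        break
      }
    }
  }
  cut
}

#' Quality-filter small-RNA reads
#'
#' Normalizes reads to upper-case DNA (U -> T), trims the 3' adapter
#' (longest exact prefix match, minimum overlap 6 nt), then keeps reads
#' that contain no N, have mean Phred quality at or above
#' `min_mean_quality` (reads without qualities pass), and are between
#' `min_len` and `max_len` nt after trimming — the 14--30 nt window of a
#' small-RNA library.
#'
#' @param reads tibble with column `seq` and optionally `qual` (Phred+33),
#'   e.g. from [read_fastq()], or a character vector of sequences.
#' @param adapter 3' adapter sequence, or `""`/`NULL` for no trimming.
#' @param min_len,max_len post-trim length window.
#' @param min_mean_quality minimum mean Phred score.
#' @return tibble of kept reads (columns as input, `seq`/`qual` trimmed)
#'   with attribute `filter_report`; see [filter_report()].
#' @export
filter_reads <- function(reads, adapter = "", min_len = 14, max_len = 30,
                         min_mean_quality = 20) {
  if (min_len > max_len) abort("`min_len` must not exceed `max_len`.")
  if (is.character(reads)) reads <- tibble(seq = reads)
  reads <- as_tibble(reads)
  n_raw <- nrow(reads)
  if (n_raw == 0) {
    out <- reads
    attr(out, "filter_report") <- tibble(raw = 0L, kept = 0L, kept_pct = NA_real_)
    return(out)
  }
  seqs <- toupper(reads$seq)
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  cut <- adapter_cut(seqs, adapter)
  trimmed <- ifelse(cut > 0, substr(seqs, 1, cut - 1L), seqs)
  has_qual <- "qual" %in% names(reads)
  qual <- if (has_qual) ifelse(cut > 0, substr(reads$qual, 1, cut - 1L),
                               reads$qual) else NULL
  len <- nchar(trimmed)
  ok_len <- len >= min_len & len <= max_len
  ok_n <- !grepl("[^ACGT]", trimmed)
  ok_q <- if (has_qual) {
    mq <- mean_phred(qual)
    is.na(mq) | mq >= min_mean_quality
  } else TRUE
  keep <- ok_len & ok_n & ok_q
  out <- reads[keep, , drop = FALSE]
  out$seq <- trimmed[keep]
  if (has_qual) out$qual <- qual[keep]
  attr(out, "filter_report") <- tibble(
    raw = n_raw, kept = sum(keep),
    kept_pct = 100 * sum(keep) / n_raw,
    discarded_length = sum(!ok_len),
    discarded_n = sum(ok_len & !ok_n),
    discarded_quality = if (has_qual) sum(ok_len & ok_n & !ok_q) else 0L)
  out
}

#' Retrieve the filtering report of a filtered read set
#'
#' @param reads output of [filter_reads()].
#' @return one-row tibble with columns `raw`, `kept`, `kept_pct` and
#'   per-rule discard counts.
#' @export
filter_report <- function(reads) {
  rep <- attr(reads, "filter_report")
  if (is.null(rep)) abort("No filter report attached; run filter_reads() first.")
  rep
}

#' Collapse clean reads into unique tags with counts
#'
#' Groups identical sequences so that each unique tag carries its total
#' read count. The total of all counts equals the number of input reads.
#'
#' @param reads tibble with column `seq`, or a character vector of reads.
#' @param label library identifier.
#' @param composition optional [genome_composition()].
#' @return a [tag_library()].
#' @export
collapse_tags <- function(reads, label = "library", composition = NULL) {
  seqs <- if (is.character(reads)) reads else as_tibble(reads)$seq
  if (length(seqs) == 0) {
    return(tag_library(tibble(seq = character(), count = integer()),
                       label, composition))
  }
  ct <- table(seqs)
  tag_library(tibble(seq = names(ct), count = as.integer(ct)),
              label, composition)
}

#' Read-length distribution of a tag library
#'
#' @param lib a `tag_library`.
#' @param weighted if `TRUE` (default) counts reads per length; if `FALSE`
#'   counts unique tags per length.
#' @param range lengths over which to tabulate (zero-filled); default 14:30.
#' @return tibble with columns `length` and `n`; `sum(n)` equals
#'   `total_reads(lib)` (weighted) or `total_unique(lib)` (unweighted).
#' @export
length_distribution <- function(lib, weighted = TRUE, range = 14:30) {
  len <- nchar(lib$seq)
  w <- if (weighted) lib$count else rep(1L, nrow(lib))
  bins <- sort(unique(c(range, len)))
  n <- vapply(bins, function(L) sum(w[len == L]), numeric(1))
  tibble(length = as.integer(bins), n = as.integer(n))
}
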