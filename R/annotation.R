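#' Map tags to a reference by exact or near-exact matching
#'
#' Matches every unique tag against the reference on both strands. With
#' `max_mismatches = 0` (default) a fast preprocessed dictionary match is
#' used ([Biostrings::matchPDict]); with mismatches allowed, each tag is
#' matched individually ([Biostrings::vmatchPattern]). A tag maps if its
#' sequence (forward) or reverse complement (minus strand) occurs in the
#' reference within the mismatch budget.
#'
#' @param lib a `tag_library`.
#' @param ref a `reference_bundle`.
#' @param max_mismatches maximum number of mismatches (default 0).
#' @return tibble of hits with columns `seq`, `count`, `seq_id`, `start`,
#'   `end`, `strand` (1-based closed coordinates); attributes carry the
#'   library label/composition, `total_reads`, `mapped_reads`,
#'   `mapped_fraction` and the `unmapped` tags. See [mapped_fraction()].
#' @export
map_tags <- function(lib, ref, max_mismatches = 0) {
  if (max_mismatches < 0) abort("`max_mismatches` must be non-negative.")
  if (length(ref$sequences) == 0) abort("Reference is empty.")
  tags <- lib$seq
  hits <- if (max_mismatches == 0) {
    exact_hits(tags, ref$sequences)
  } else {
    mismatch_hits(tags, ref$sequences, max_mismatches)
  }
  hits <- left_join(hits, tibble(seq = lib$seq, count = lib$count),
                    by = "seq")
  hits <- hits[c("seq", "count", "seq_id", "start", "end", "strand")]
  hits <- arrange(hits, .data$seq, .data$seq_id, .data$start, .data$strand)
  mapped_tags <- unique(hits$seq)
  mapped_reads <- sum(lib$count[lib$seq %in% mapped_tags])
  structure(hits,
            label = lib_label(lib),
            composition = attr(lib, "composition"),
            total_reads = total_reads(lib),
            mapped_reads = mapped_reads,
            mapped_fraction = mapped_reads / total_reads(lib),
            unmapped = lib[!(lib$seq %in% mapped_tags),
                           c("seq", "count")],
            class = class(hits))
}

# All exact occurrences of `tags` in `subjects` (DNAStringSet), both strands.
exact_hits <- function(tags, subjects) {
  if (length(tags) == 0) {
    return(tibble(seq = character(), seq_id = character(),
                  start = integer(), end = integer(), strand = character()))
  }
  widths <- nchar(tags)
  out <- list()
  for (w in unique(widths)) {
    grp <- tags[widths == w]
    sets <- list(`+` = Biostrings::DNAStringSet(grp),
                 `-` = Biostrings::reverseComplement(
                         Biostrings::DNAStringSet(grp)))
    for (strand in names(sets)) {
      pd <- Biostrings::PDict(sets[[strand]])
      for (sid in names(subjects)) {
        m <- Biostrings::matchPDict(pd, subjects[[sid]])
        nh <- S4Vectors::elementNROWS(m)
        if (sum(nh) == 0) next
        ir <- unlist(m)
        out[[length(out) + 1]] <- tibble(
          seq = rep(grp, nh),
          seq_id = sid,
          start = BiocGenerics::start(ir),
          end = BiocGenerics::end(ir),
          strand = strand)
      }
    }
  }
  if (!length(out)) {
    return(tibble(seq = character(), seq_id = character(),
                  start = integer(), end = integer(), strand = character()))
  }
  distinct(bind_rows(out))
}

mismatch_hits <- function(tags, subjects, max_mismatches) {
  out <- list()
  for (tag in tags) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") tag else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(tag)))
      for (sid in names(subjects)) {
        ir <- Biostrings::matchPattern(pat, subjects[[sid]],
                                       max.mismatch = max_mismatches,
                                       with.indels = FALSE)
        if (length(ir) == 0) next
        out[[length(out) + 1]] <- tibble(
          seq = tag, seq_id = sid,
          start = BiocGenerics::start(ir), end = BiocGenerics::end(ir),
          strand = strand)
      }
    }
  }
  if (!length(out)) {
    return(tibble(seq = character(), seq_id = character(),
                  start = integer(), end = integer(), strand = character()))
  }
  distinct(bind_rows(out))
}

#' @rdname map_tags
#' @param hits output of `map_tags()`.
#' @return for `mapped_fraction()`: the fraction of reads whose tag has at
#'   least one hit.
#' @export
mapped_fraction <- function(hits) attr(hits, "mapped_fraction")

#' Assign one annotation category per mapped tag
#'
#' Pools the categories of all features overlapping any of a tag's hits and
#' assigns the single highest-priority category in the order rRNA, tRNA,
#' snRNA, snoRNA, mRNA (structural/housekeeping classes), then miRNA, then
#' repeat, exon, intron. miRNA assignments carry the mature-miRNA name and
#' require the hit strand to equal the feature strand; other categories are
#' strand-agnostic. Mapped tags overlapping no feature are "unannotated".
#' Ties within a category break to the feature with the lowest
#' (seq_id, start), so output is deterministic.
#'
#' @param hits tag hits from [map_tags()] (on the same reference).
#' @param ref the `reference_bundle` used for mapping.
#' @return an `annotated_library`: tibble with one row per mapped tag
#'   (columns `seq`, `count`, `category`, `feature`), with library
#'   attributes carried over.
#' @export
annotate_tags <- function(hits, ref) {
  unknown <- setdiff(unique(hits$seq_id), names(ref$sequences))
  if (length(unknown)) {
    abort(sprintf("Hits reference unknown sequence(s): %s.",
                  paste(unknown, collapse = ", ")),
          class = "polymir_inconsistent_reference")
  }
  tags <- distinct(as_tibble(hits)[c("seq", "count")])
  if (nrow(hits) == 0) {
    assignments <- tibble(seq = character(), count = integer(),
                          category = character(), feature = character())
  } else {
    hit_gr <- GenomicRanges::GRanges(
      hits$seq_id, IRanges::IRanges(hits$start, hits$end),
      strand = hits$strand)
    feat <- ref$features
    feat_gr <- GenomicRanges::GRanges(
      feat$seq_id, IRanges::IRanges(feat$start, feat$end),
      strand = feat$strand)
    fo <- GenomicRanges::findOverlaps(hit_gr, feat_gr, ignore.strand = TRUE)
    q <- S4Vectors::queryHits(fo)
    s <- S4Vectors::subjectHits(fo)
    # mature miRNAs are strand-defined; other categories are not
    strand_ok <- feat$category[s] != "miRNA" |
      hits$strand[q] == feat$strand[s]
    q <- q[strand_ok]; s <- s[strand_ok]
    ov <- tibble(seq = hits$seq[q],
                 category = feat$category[s],
                 feature = feat$name[s],
                 f_seq_id = feat$seq_id[s],
                 f_start = feat$start[s]) %>%
      mutate(priority = match(.data$category, CATEGORY_PRIORITY)) %>%
      arrange(.data$priority, .data$f_seq_id, .data$f_start) %>%
      distinct(.data$seq, .keep_all = TRUE)
    assignments <- tags %>%
      left_join(ov[c("seq", "category", "feature")], by = "seq") %>%
      mutate(category = ifelse(is.na(.data$category), "unannotated",
                               .data$category),
             feature = ifelse(.data$category == "miRNA", .data$feature,
                              NA_character_))
  }
  structure(as_tibble(assignments),
            label = attr(hits, "label"),
            composition = attr(hits, "composition"),
            total_reads = attr(hits, "total_reads"),
            mapped_reads = attr(hits, "mapped_reads"),
            mapped_fraction = attr(hits, "mapped_fraction"),
            unmapped = attr(hits, "unmapped"),
            class = c("annotated_library", class(as_tibble(assignments))))
}

#' @export
print.annotated_library <- function(x, ...) {
  cat(sprintf("<annotated_library> %s: %d mapped tags (%.1f%% of reads mapped)\n",
              lib_label(x), nrow(x), 100 * (attr(x, "mapped_fraction") %||% NA)))
  NextMethod()
}

#' Per-category annotation summary
#'
#' Tabulates unique tags, read counts and the percentage of total clean
#' reads per annotation category, including "unannotated" (mapped but
#' overlapping no feature) and "unmapped". Rows sum to the library totals.
#'
#' @param annotated an `annotated_library` from [annotate_tags()].
#' @return tibble with columns `category`, `unique_tags`, `reads`,
#'   `pct_reads`.
#' @export
category_summary <- function(annotated) {
  total <- attr(annotated, "total_reads")
  unmapped <- attr(annotated, "unmapped") %||% tibble(seq = character(),
                                                      count = integer())
  cats <- c(CATEGORY_PRIORITY, "unannotated", "unmapped")
  per <- annotated %>%
    group_by(.data$category) %>%
    summarise(unique_tags = dplyr::n(), reads = sum(.data$count),
              .groups = "drop")
  per <- bind_rows(per, tibble(category = "unmapped",
                               unique_tags = nrow(unmapped),
                               reads = sum(unmapped$count)))
  out <- tibble(category = cats) %>%
    left_join(per, by = "category") %>%
    mutate(unique_tags = ifelse(is.na(.data$unique_tags), 0L,
                                .data$unique_tags),
           reads = ifelse(is.na(.data$reads), 0L, .data$reads),
           pct_reads = if (isTRUE(total > 0)) 100 * .data$reads / total
                       else 0)
  out
}
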