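#' Construct a tag library
#'
#' A tag library is the collapsed form of a small-RNA read library: one row
#' per unique sequence ("tag") with its total read count. It is stored as a
#' tibble with columns `seq` and `count`, carrying the library label and
#' genome composition as attributes.
#'
#' @param tags a data frame with columns `seq` (character, A/C/G/T) and
#'   `count` (positive integers).
#' @param label library identifier.
#' @param composition a [genome_composition()] (or something coercible).
#'
#' @return a `tag_library`: a tibble with columns `seq`, `count` sorted by
#'   decreasing count, with attributes `label`, `composition`,
#'   `total_reads`, `total_unique`.
#' @export
tag_library <- function(tags, label, composition = NULL) {
  tags <- as_tibble(tags)
  stopifnot(all(c("seq", "count") %in% names(tags)))
  if (anyDuplicated(tags$seq)) {
    abort("Tag sequences must be unique; collapse reads first.")
  }
  if (any(tags$count < 1 | tags$count != floor(tags$count))) {
    abort("Tag counts must be positive integers.")
  }
  if (nrow(tags) && any(grepl("[^ACGT]", tags$seq))) {
    abort("Tag sequences must be over the alphabet {A,C,G,T}.")
  }
  tags <- arrange(tags[c("seq", "count")], dplyr::desc(.data$count), .data$seq)
  tags$count <- as.integer(tags$count)
  structure(tags,
            label = label,
            composition = if (!is.null(composition))
              genome_composition(composition) else NULL,
            total_reads = sum(tags$count),
            total_unique = nrow(tags),
            class = c("tag_library", class(tags)))
}

#' @export
print.tag_library <- function(x, ...) {
  cat(sprintf("<tag_library> %s: %d unique tags, %d reads\n",
              lib_label(x), attr(x, "total_unique"), attr(x, "total_reads")))
  NextMethod()
}

lib_label <- function(x) attr(x, "label") %||% "<unlabelled>"

#' Total reads and unique tags of a library
#'
#' @param lib a `tag_library`.
#' @return an integer count.
#' @export
total_reads <- function(lib) attr(lib, "total_reads")

#' @rdname total_reads
#' @export
total_unique <- function(lib) attr(lib, "total_unique")

#' Expand a tag library back into individual reads
#'
#' Inverse of [collapse_tags()]: repeats each unique tag by its read count.
#' Mainly useful for round-trip checks and for recomputing read-weighted
#' statistics by brute force.
#'
#' @param lib a `tag_library`.
#' @return a character vector of reads, `total_reads(lib)` long.
#' @export
expand_tags <- function(lib) {
  rep(lib$seq, lib$count)
}
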