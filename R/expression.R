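#' Construct an expression profile from miRNA read counts
#'
#' The expression level of each miRNA is its read count divided by the
#' total reads of all miRNAs in the same library, so a profile is a
#' proportion vector summing to 1.
#'
#' @param counts named numeric vector of per-miRNA read counts (or an
#'   equivalent two-column data frame `mirna`/`reads`).
#' @param label library identifier.
#' @param composition optional [genome_composition()].
#' @return an `expression_profile`: tibble with columns `mirna`, `reads`,
#'   `proportion`, and attributes `label`, `composition`,
#'   `total_mirna_reads`.
#' @export
expression_profile <- function(counts, label, composition = NULL) {
  if (is.data.frame(counts)) {
    counts <- setNames(counts$reads, counts$mirna)
  }
  if (is.null(names(counts)) || any(counts < 0)) {
    abort("`counts` must be a named vector of non-negative read counts.")
  }
  total <- sum(counts)
  if (total <= 0) {
    abort(sprintf("Library '%s' has no miRNA reads; cannot form a profile.",
                  label),
          class = "polymir_degenerate_library")
  }
  out <- tibble(mirna = names(counts), reads = as.numeric(counts),
                proportion = as.numeric(counts) / total)
  structure(out,
            label = label,
            composition = if (!is.null(composition))
              genome_composition(composition) else NULL,
            total_mirna_reads = total,
            class = c("expression_profile", class(out)))
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("<expression_profile> %s: %d miRNAs, %s miRNA reads\n",
              lib_label(x), nrow(x),
              format(attr(x, "total_mirna_reads"), big.mark = ",")))
  NextMethod()
}

#' miRNA reads underlying a profile
#' @param profile an `expression_profile`.
#' @return total miRNA-assigned read count.
#' @export
total_mirna_reads <- function(profile) attr(profile, "total_mirna_reads")

#' miRNA expression profile of an annotated library
#'
#' Sums read counts over tags assigned to each mature miRNA and normalizes
#' by the library's total miRNA reads.
#'
#' @param annotated an `annotated_library` from [annotate_tags()].
#' @param universe optional character vector of miRNA names to report;
#'   names absent from the library get proportion 0. Defaults to the
#'   miRNAs observed in the library.
#' @return an `expression_profile`.
#' @export
mirna_expression <- function(annotated, universe = NULL) {
  mir <- annotated %>%
    filter(.data$category == "miRNA") %>%
    group_by(mirna = .data$feature) %>%
    summarise(reads = sum(.data$count), .groups = "drop")
  if (nrow(mir) == 0 || sum(mir$reads) == 0) {
    abort(sprintf("Library '%s' has no miRNA-assigned reads.",
                  lib_label(annotated)),
          class = "polymir_degenerate_library")
  }
  counts <- setNames(mir$reads, mir$mirna)
  if (!is.null(universe)) {
    full <- setNames(numeric(length(universe)), universe)
    full[intersect(names(counts), universe)] <-
      counts[intersect(names(counts), universe)]
    counts <- full
  }
  prof <- expression_profile(counts, label = lib_label(annotated),
                             composition = attr(annotated, "composition"))
  # denominator stays the library's total miRNA reads, universe or not
  attr(prof, "total_mirna_reads") <- sum(mir$reads)
  prof$proportion <- prof$reads / sum(mir$reads)
  prof
}

#' Cross-library miRNA expression matrix
#'
#' Assembles profiles into a miRNA-by-library table. By default rows are
#' restricted to the comparative universe: miRNAs detected (count > 0) in
#' every library, emulating a conserved-miRNA set identified in all
#' libraries. Proportions are not renormalized after restriction (each
#' library's values still divide by its total miRNA reads) unless
#' `renormalize = TRUE`.
#'
#' @param profiles list of `expression_profile` objects.
#' @param universe optional explicit miRNA name vector; a name absent from
#'   every profile triggers a warning and a row of zeros.
#' @param renormalize rescale each column to sum to 1 over the universe.
#' @return tibble with column `mirna` plus one proportion column per
#'   library label.
#' @export
expression_matrix <- function(profiles, universe = NULL,
                              renormalize = FALSE) {
  if (length(profiles) < 1) abort("Need at least one profile.")
  labels <- vapply(profiles, lib_label, character(1))
  if (anyDuplicated(labels)) abort("Profile labels must be unique.")
  if (is.null(universe)) {
    detected <- lapply(profiles, function(p) p$mirna[p$reads > 0])
    universe <- Reduce(intersect, detected)
  } else {
    everywhere_absent <- !universe %in%
      unique(unlist(lapply(profiles, function(p) p$mirna)))
    if (any(everywhere_absent)) {
      warn(sprintf("miRNA(s) absent from all profiles: %s.",
                   paste(universe[everywhere_absent], collapse = ", ")))
    }
  }
  out <- tibble(mirna = universe)
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    v <- setNames(p$proportion, p$mirna)[universe]
    v[is.na(v)] <- 0
    if (renormalize && sum(v) > 0) v <- v / sum(v)
    out[[labels[i]]] <- unname(v)
  }
  out
}

#' Extract one library's profile from an expression matrix
#'
#' @param mat output of [expression_matrix()].
#' @param label a library column name.
#' @return named numeric proportion vector.
#' @export
matrix_column <- function(mat, label) {
  if (!label %in% names(mat)) abort(sprintf("No column '%s'.", label))
  setNames(mat[[label]], mat$mirna)
}
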