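#' Genome compositions of a hybrid polyploid complex
#'
#' A genome composition records how many copies of each parental genome an
#' individual carries, e.g. a triploid hybrid with one P and two A genomes
#' (label "PAA", dosage P = 1, A = 2). The dosage weights drive the
#' mid-parent additivity expectation: a hybrid expressing additively is
#' expected at the dosage-weighted mean of its parental profiles.
#'
#' @param x either a named non-negative integer vector of genome dosages
#'   (e.g. `c(P = 1, A = 2)`), a compact label such as `"PAA"` (one letter
#'   per genome copy), or a `"P:1,A:2"` style string.
#' @param label optional display label; defaults to the letters repeated by
#'   dosage (e.g. `"PAA"`).
#'
#' @return an object of class `genome_composition`: a list with elements
#'   `label` and `dosage` (named integer vector).
#' @examples
#' genome_composition("PAA")
#' genome_composition(c(P = 1, A = 2))
#' @export
genome_composition <- function(x, label = NULL) {
  if (inherits(x, "genome_composition")) return(x)
  if (is.character(x) && length(x) == 1) {
    if (grepl(":", x, fixed = TRUE)) {
      parts <- strsplit(x, ",", fixed = TRUE)[[1]]
      kv <- strsplit(trimws(parts), ":", fixed = TRUE)
      dosage <- vapply(kv, function(p) as.numeric(p[2]), numeric(1))
      names(dosage) <- vapply(kv, function(p) trimws(p[1]), character(1))
    } else {
      letters_ <- strsplit(x, "")[[1]]
      dosage <- table(factor(letters_, levels = unique(letters_)))
      dosage <- setNames(as.numeric(dosage), names(dosage))
      label <- label %||% x
    }
  } else if (is.numeric(x) && !is.null(names(x))) {
    dosage <- x
  } else {
    abort("`x` must be a named dosage vector or a composition string.")
  }
  if (any(is.na(dosage)) || any(dosage < 0) || any(dosage != floor(dosage))) {
    abort("Genome dosages must be non-negative integers.",
          class = "polymir_invalid_dosage")
  }
  if (sum(dosage) < 1) {
    abort("Total genome dosage must be at least 1.",
          class = "polymir_invalid_dosage")
  }
  dosage <- setNames(as.integer(dosage), names(dosage))
  label <- label %||% paste(rep(names(dosage), dosage), collapse = "")
  structure(list(label = label, dosage = dosage),
            class = "genome_composition")
}

#' @export
print.genome_composition <- function(x, ...) {
  cat("<genome_composition> ", x$label, " (",
      paste(sprintf("%s:%d", names(x$dosage), x$dosage), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' @export
format.genome_composition <- function(x, ...) {
  paste(sprintf("%s:%d", names(x$dosage), x$dosage), collapse = ",")
}

total_dosage <- function(composition) sum(composition$dosage)

# TRUE when the composition carries copies of a single parental genome
# (a non-hybrid form, usable as the parental expression reference).
is_pure <- function(composition) sum(composition$dosage > 0) == 1
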