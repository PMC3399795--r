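#' Write a reference bundle as FASTA plus GFF3
#'
#' Features are written 1-based closed (GFF3 convention) with the category
#' in the `type` column and, for miRNAs, the mature name in the `Name`
#' attribute.
#'
#' @param ref a `reference_bundle`.
#' @param fasta_path,gff_path output paths.
#' @return invisibly, the two paths.
#' @export
write_reference <- function(ref, fasta_path, gff_path) {
  Biostrings::writeXStringSet(ref$sequences, fasta_path)
  gr <- GenomicRanges::GRanges(
    ref$features$seq_id,
    IRanges::IRanges(ref$features$start, ref$features$end),
    strand = ref$features$strand,
    type = ref$features$category,
    source = "polymir",
    Name = ref$features$name,
    ID = ref$features$name)
  rtracklayer::export(gr, gff_path, format = "gff3")
  invisible(c(fasta = fasta_path, gff = gff_path))
}

#' Read a reference bundle from FASTA plus GFF3/BED
#'
#' GFF3 features carry their category in the `type` column and names in
#' the `Name` attribute. BED input (0-based half-open, converted on
#' import) carries `"category"` or `"category:name"` in its name field.
#'
#' @param fasta_path reference FASTA.
#' @param features_path GFF3 (`.gff`, `.gff3`) or BED (`.bed`) file.
#' @return a `reference_bundle`.
#' @export
read_reference <- function(fasta_path, features_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  is_bed <- grepl("\\.bed(\\.gz)?$", features_path, ignore.case = TRUE)
  gr <- rtracklayer::import(features_path,
                            format = if (is_bed) "bed" else "gff3")
  md <- S4Vectors::mcols(gr)
  if (is_bed) {
    raw <- as.character(md$name)
    category <- sub(":.*$", "", raw)
    name <- ifelse(grepl(":", raw), sub("^[^:]*:", "", raw), raw)
  } else {
    category <- as.character(md$type)
    name <- if ("Name" %in% names(md)) as.character(md$Name)
            else as.character(md$ID)
  }
  features <- tibble(
    category = category,
    name = name,
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)))
  features$strand[features$strand == "*"] <- "+"
  reference_bundle(seqs, features)
}

#' Write a tag library as collapsed FASTA
#'
#' Headers follow the `>tag{serial}_x{count}` convention, tags ordered by
#' decreasing count.
#'
#' @param lib a `tag_library`.
#' @param path output FASTA path.
#' @return invisibly, `path`.
#' @export
write_collapsed_fasta <- function(lib, path) {
  headers <- sprintf(">tag%d_x%d", seq_len(nrow(lib)), lib$count)
  writeLines(as.vector(rbind(headers, lib$seq)), path)
  invisible(path)
}

#' Read a collapsed FASTA into a tag library
#'
#' Expects `_x{count}` header suffixes; a header without one counts as a
#' single read.
#'
#' @param path collapsed FASTA path.
#' @param label library identifier.
#' @param composition optional [genome_composition()].
#' @return a `tag_library`.
#' @export
read_collapsed_fasta <- function(path, label = basename(path),
                                 composition = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  counts <- suppressWarnings(
    as.integer(sub("^.*_x(\\d+)\\s*$", "\\1", names(seqs))))
  counts[is.na(counts)] <- 1L
  tags <- tibble(seq = as.character(seqs), count = counts) %>%
    group_by(.data$seq) %>%
    summarise(count = sum(.data$count), .groups = "drop")
  tag_library(tags, label, composition)
}

#' Write reads as FASTQ
#'
#' Phred+33 with constant quality `"I"` (Q40); gzipped when the path ends
#' in `.gz`.
#'
#' @param reads character vector of read sequences, or a `tag_library`
#'   (expanded to reads).
#' @param path output path.
#' @param ids optional read identifiers.
#' @return invisibly, `path`.
#' @export
write_fastq <- function(reads, path, ids = NULL) {
  if (inherits(reads, "tag_library")) reads <- expand_tags(reads)
  ids <- ids %||% sprintf("read%d", seq_along(reads))
  rec <- as.vector(rbind(paste0("@", ids), reads, "+",
                         strrep("I", nchar(reads))))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(rec, con)
  invisible(path)
}
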