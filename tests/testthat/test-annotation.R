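# A small hand-laid reference: one 120-bp chromosome with features at known
# coordinates, used for exact-coordinate and priority-rule checks.
toy_reference <- function() {
  set.seed(71)
  chrom <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  features <- tibble::tibble(
    category = c("rRNA", "miRNA", "repeat", "exon", "miRNA"),
    name = c("rRNA_1", "mir-a", "rep_1", "exon_1", "mir-b"),
    seq_id = "ref_1",
    start = c(10L, 25L, 60L, 70L, 95L),
    end = c(30L, 46L, 80L, 90L, 116L),
    strand = c("+", "+", "+", "+", "+"))
  reference_bundle(Biostrings::DNAStringSet(c(ref_1 = chrom)), features)
}

toy_tag <- function(ref, start, end, revcomp = FALSE) {
  s <- substr(as.character(ref$sequences[["ref_1"]]), start, end)
  if (revcomp) s <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

test_that("map_tags finds exact hits at correct coordinates on both strands", {
  ref <- toy_reference()
  fwd <- toy_tag(ref, 25, 46)
  rev <- toy_tag(ref, 60, 80, revcomp = TRUE)
  lib <- make_library(c(fwd, rev, strrep("ACGTT", 4)), label = "toy")
  hits <- map_tags(lib, ref)
  h_fwd <- hits[hits$seq == fwd, ]
  expect_true(any(h_fwd$start == 25 & h_fwd$end == 46 & h_fwd$strand == "+"))
  h_rev <- hits[hits$seq == rev, ]
  expect_true(any(h_rev$start == 60 & h_rev$end == 80 & h_rev$strand == "-"))
  expect_error(map_tags(lib, ref, max_mismatches = -1))
})

test_that("random tags absent from the reference stay unmapped", {
  ref <- toy_reference()
  lib <- make_library(random_reads(5), label = "miss")
  hits <- map_tags(lib, ref)
  expect_equal(nrow(hits), 0)
  expect_equal(mapped_fraction(hits), 0)
  expect_equal(nrow(attr(hits, "unmapped")), 5)
})

test_that("near-exact matching admits the mismatch budget", {
  ref <- toy_reference()
  tag <- toy_tag(ref, 25, 46)
  mutated <- paste0(ifelse(substr(tag, 1, 1) == "A", "C", "A"),
                    substr(tag, 2, nchar(tag)))
  lib <- make_library(mutated, label = "mm")
  expect_equal(nrow(map_tags(lib, ref, max_mismatches = 0)), 0)
  h1 <- map_tags(lib, ref, max_mismatches = 1)
  expect_true(any(h1$start == 25 & h1$end == 46))
})

test_that("the priority rule resolves multi-category overlaps", {
  ref <- toy_reference()
  # spans the rRNA/miRNA overlap zone (25..30 in both)
  both <- toy_tag(ref, 26, 40)            # miRNA only? 26..40 within mir-a;
  over <- toy_tag(ref, 14, 28)            # overlaps rRNA (10-30) and mir-a (25-46)
  repx <- toy_tag(ref, 72, 86)            # overlaps repeat (60-80) and exon (70-90)
  mirb <- toy_tag(ref, 95, 116)           # pure miRNA
  lib <- make_library(c(over, repx, mirb, both), label = "prio")
  ann <- annotate_tags(map_tags(lib, ref), ref)
  get_cat <- function(s) ann$category[ann$seq == s]
  expect_equal(get_cat(over), "rRNA")     # structural RNA outranks miRNA
  expect_equal(get_cat(repx), "repeat")   # repeat > exon
  expect_equal(get_cat(mirb), "miRNA")
  expect_equal(ann$feature[ann$seq == mirb], "mir-b")
})

test_that("miRNA assignment is strand-aware, other categories are not", {
  ref <- toy_reference()
  mir_rc <- toy_tag(ref, 95, 116, revcomp = TRUE)   # hits mir-b on minus
  rep_rc <- toy_tag(ref, 61, 79, revcomp = TRUE)    # hits repeat on minus
  lib <- make_library(c(mir_rc, rep_rc), label = "strand")
  ann <- annotate_tags(map_tags(lib, ref), ref)
  expect_equal(ann$category[ann$seq == mir_rc], "unannotated")
  expect_equal(ann$category[ann$seq == rep_rc], "repeat")
})

test_that("priority monotonicity: lower-priority features never change an assignment", {
  ref <- toy_reference()
  tag <- toy_tag(ref, 95, 116)   # overlaps only mir-b
  lib <- make_library(tag, label = "mono")
  base_cat <- annotate_tags(map_tags(lib, ref), ref)$category
  expect_equal(base_cat, "miRNA")
  # add an overlapping intron (lower priority than miRNA): no change
  f2 <- dplyr::bind_rows(ref$features,
                         tibble::tibble(category = "intron", name = "int_1",
                                        seq_id = "ref_1", start = 90L,
                                        end = 120L, strand = "+"))
  ref2 <- reference_bundle(ref$sequences, f2)
  expect_equal(annotate_tags(map_tags(lib, ref2), ref2)$category, base_cat)
  # add an overlapping tRNA (higher priority): assignment changes
  f3 <- dplyr::bind_rows(ref$features,
                         tibble::tibble(category = "tRNA", name = "trna_1",
                                        seq_id = "ref_1", start = 90L,
                                        end = 120L, strand = "+"))
  ref3 <- reference_bundle(ref$sequences, f3)
  expect_equal(annotate_tags(map_tags(lib, ref3), ref3)$category, "tRNA")
})

test_that("annotation agrees with a brute-force oracle on random fixtures", {
  set.seed(83)
  chrom <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  seqs <- Biostrings::DNAStringSet(c(ref_1 = chrom))
  cats <- c("rRNA", "tRNA", "snRNA", "snoRNA", "mRNA", "miRNA", "repeat",
            "exon", "intron")
  for (i in 1:100) {
    nf <- sample(3:8, 1)
    start <- sort(sample(1:360, nf))
    features <- tibble::tibble(
      category = sample(cats, nf, replace = TRUE),
      name = sprintf("f%d", seq_len(nf)),
      seq_id = "ref_1",
      start = start,
      end = pmin(400L, start + sample(15:60, nf, replace = TRUE)),
      strand = sample(c("+", "-"), nf, replace = TRUE))
    features$name[features$category == "miRNA"] <-
      sprintf("mir-%d", seq_len(sum(features$category == "miRNA")))
    ref <- reference_bundle(seqs, features)
    nt <- sample(2:6, 1)
    hstart <- sample(1:380, nt)
    hits <- tibble::tibble(
      seq = sprintf("tag%d", seq_len(nt)),
      count = sample(1:10, nt, replace = TRUE),
      seq_id = "ref_1",
      start = hstart,
      end = pmin(400L, hstart + sample(14:25, nt, replace = TRUE)),
      strand = sample(c("+", "-"), nt, replace = TRUE))
    ann <- annotate_tags(hits, ref)
    orc <- oracle_annotate(hits, features)
    for (tag in names(orc)) {
      expect_equal(ann$category[ann$seq == tag], orc[[tag]],
                   info = sprintf("instance %d tag %s", i, tag))
    }
  }
})

test_that("contaminant-free simulated libraries map fully as miRNA", {
  ref <- simulate_reference(25, 5, seed = 19)
  mirnas <- names(mirna_sequences(ref))
  p <- random_parental_proportions(mirnas, "P", seed = 20)$P
  lib <- simulate_library(p, ref, 8000, contaminant_fraction = 0, seed = 21)
  hits <- map_tags(lib, ref)
  expect_equal(mapped_fraction(hits), 1.0)
  ann <- annotate_tags(hits, ref)
  summ <- category_summary(ann)
  expect_equal(summ$reads[summ$category == "miRNA"], 8000)
  expect_equal(sum(summ$reads), total_reads(lib))
  # one-annotation rule: each tag appears exactly once
  expect_equal(anyDuplicated(ann$seq), 0)
})

test_that("category read counts match the generator's ground-truth tally", {
  ref <- simulate_reference(20, 10, seed = 23)
  mirnas <- names(mirna_sequences(ref))
  p <- random_parental_proportions(mirnas, "P", seed = 24)$P
  lib <- simulate_library(p, ref, 6000, contaminant_fraction = 0.3, seed = 25)
  truth <- attr(lib, "simulated_truth")
  ann <- annotate_tags(map_tags(lib, ref), ref)
  summ <- category_summary(ann)
  expect_equal(summ$reads[summ$category == "miRNA"],
               unname(sum(truth$mirna_counts)))
  for (cat in names(truth$contaminant_counts_by_category)) {
    expect_equal(summ$reads[summ$category == cat],
                 unname(truth$contaminant_counts_by_category[[cat]]),
                 info = cat)
  }
})

test_that("hits against an unknown sequence are rejected", {
  ref <- toy_reference()
  hits <- tibble::tibble(seq = "ACGT", count = 1L, seq_id = "nope",
                         start = 1L, end = 4L, strand = "+")
  expect_error(annotate_tags(hits, ref),
               class = "polymir_inconsistent_reference")
})
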