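#' Default read-length model for simulated small-RNA libraries
#'
#' Discrete distribution over read lengths 14--30 nt with its mode at 22 nt
#' and more than half of the mass on 20--23 nt, matching the length profile
#' of a good small-RNA library in which mature miRNAs (20--23 nt, mostly
#' 22 nt) dominate over degradation products of other RNA classes.
#'
#' @return a named numeric probability vector over lengths `"14"`..`"30"`.
#' @export
default_length_model <- function() {
  w <- c(0.5, 0.7, 1, 1.5, 2, 3,      # 14-19: low-level degradation tail
         8, 12, 28, 9,                # 20-23: the miRNA peak, mode at 22
         3, 2.5, 2, 1.5, 1.2, 1, 0.8) # 24-30: longer fragments
  setNames(w / sum(w), as.character(14:30))
}

#' Ground truth for a simulated small-RNA study
#'
#' Bundles everything the synthetic-data generator needs: the miRNA universe,
#' the true per-genome miRNA proportion vectors, a set of non-additive
#' effects to plant in named hybrids, the contaminant read fraction and the
#' read-length model.
#'
#' @param mirna_names character vector of miRNA identifiers.
#' @param parental_proportions named list (one element per parental genome
#'   symbol) of numeric vectors of true miRNA proportions; each must be
#'   named by `mirna_names` and sum to 1 within 1e-9.
#' @param nonadditive_set named list (one element per hybrid label) of named
#'   numeric vectors of log2 effects applied multiplicatively on top of the
#'   additive mixture in that hybrid. Default: no planted effects.
#' @param contaminant_fraction fraction of reads per library drawn from
#'   non-miRNA features; in `[0, 1)`.
#' @param length_model probability vector over read lengths 14--30 used for
#'   contaminant reads; see [default_length_model()].
#'
#' @return an object of class `simulation_truth`.
#' @export
simulation_truth <- function(mirna_names, parental_proportions,
                             nonadditive_set = list(),
                             contaminant_fraction = 0.15,
                             length_model = default_length_model()) {
  stopifnot(is.character(mirna_names), length(mirna_names) >= 1)
  for (g in names(parental_proportions)) {
    p <- parental_proportions[[g]]
    if (!setequal(names(p), mirna_names)) {
      abort(sprintf("Proportions for genome '%s' must be named by `mirna_names`.", g))
    }
    if (abs(sum(p) - 1) > 1e-9 || any(p < 0)) {
      abort(sprintf("Proportions for genome '%s' must be non-negative and sum to 1.", g))
    }
    parental_proportions[[g]] <- p[mirna_names]
  }
  for (h in names(nonadditive_set)) {
    eff <- nonadditive_set[[h]]
    if (!all(names(eff) %in% mirna_names) || !all(is.finite(eff))) {
      abort(sprintf("Non-additive effects for '%s' must be finite and named by known miRNAs.", h))
    }
  }
  if (!is.numeric(contaminant_fraction) || contaminant_fraction < 0 ||
      contaminant_fraction >= 1) {
    abort("`contaminant_fraction` must lie in [0, 1).")
  }
  structure(list(mirna_names = mirna_names,
                 parental_proportions = parental_proportions,
                 nonadditive_set = nonadditive_set,
                 contaminant_fraction = contaminant_fraction,
                 length_model = length_model),
            class = "simulation_truth")
}

#' Draw random parental miRNA proportion vectors
#'
#' True proportions are drawn log-normal (meanlog 0, sdlog 1) and
#' normalized, giving the several-orders-of-magnitude dynamic range typical
#' of miRNA expression.
#'
#' @param mirna_names miRNA identifiers.
#' @param symbols parental genome symbols, e.g. `c("P", "A")`.
#' @param seed RNG seed (NULL to use the current RNG state).
#' @param sdlog log-scale standard deviation of the draw.
#' @return named list of proportion vectors, one per symbol.
#' @export
random_parental_proportions <- function(mirna_names, symbols = c("P", "A"),
                                        seed = NULL, sdlog = 1) {
  with_seed(seed, {
    lapply(setNames(symbols, symbols), function(g) {
      x <- rlnorm(length(mirna_names), meanlog = 0, sdlog = sdlog)
      setNames(x / sum(x), mirna_names)
    })
  })
}

#' Simulate a categorized reference sequence
#'
#' Builds a single synthetic reference chromosome carrying `n_mirnas`
#' non-overlapping mature-miRNA features (20--23 nt, most of them 22 nt)
#' and `n_contaminant_features` longer features cycling through the
#' categories rRNA, tRNA, repeat, exon and intron, separated by random
#' spacer sequence. All feature sequences are pairwise distinct and the
#' output is deterministic given `seed`.
#'
#' @param n_mirnas number of miRNA features (>= 1).
#' @param n_contaminant_features number of non-miRNA features (>= 0).
#' @param seed RNG seed.
#' @return a `reference_bundle`: list with `sequences` (a
#'   [Biostrings::DNAStringSet] with one chromosome) and `features`
#'   (tibble with columns `category`, `name`, `seq_id`, `start`, `end`,
#'   `strand`; 1-based closed coordinates).
#' @export
simulate_reference <- function(n_mirnas, n_contaminant_features = 0,
                               seed = NULL) {
  assert_positive_int(n_mirnas, "n_mirnas")
  stopifnot(n_contaminant_features >= 0)
  with_seed(seed, {
    mir_lengths <- sample(20:23, n_mirnas, replace = TRUE,
                          prob = c(0.13, 0.18, 0.55, 0.14))
    mir_seqs <- vapply(mir_lengths, function(L) random_dna(1, L), character(1))
    # feature sequences must be pairwise distinct
    for (i in seq_len(100)) {
      dup <- duplicated(mir_seqs)
      if (!any(dup)) break
      mir_seqs[dup] <- vapply(mir_lengths[dup], function(L) random_dna(1, L),
                              character(1))
    }
    if (anyDuplicated(mir_seqs)) abort("Could not draw distinct miRNA sequences.")

    cats <- c("rRNA", "tRNA", "repeat", "exon", "intron")
    base_len <- c(rRNA = 600, tRNA = 80, "repeat" = 250, exon = 180,
                  intron = 350)
    n_c <- n_contaminant_features
    contam_cat <- if (n_c > 0) cats[(seq_len(n_c) - 1) %% length(cats) + 1]
                  else character(0)
    contam_len <- vapply(contam_cat, function(cc) {
      max(30L, as.integer(round(base_len[[cc]] * runif(1, 0.8, 1.2))))
    }, integer(1))
    contam_seqs <- vapply(contam_len, function(L) random_dna(1, L),
                          character(1))
    contam_name <- if (n_c > 0) {
      stats::ave(contam_cat, contam_cat,
                 FUN = function(v) sprintf("%s_%d", v, seq_along(v)))
    } else character(0)

    feat <- tibble(
      category = c(rep("miRNA", n_mirnas), contam_cat),
      name = c(sprintf("mir-%03d", seq_len(n_mirnas)), contam_name),
      seq = c(mir_seqs, contam_seqs))
    feat <- feat[sample.int(nrow(feat)), ]  # interleave categories

    widths <- nchar(feat$seq)
    gaps <- sample(20:60, nrow(feat) + 1, replace = TRUE)
    starts <- integer(nrow(feat))
    pieces <- character(2 * nrow(feat) + 1)
    pos <- 1L
    for (i in seq_len(nrow(feat))) {
      spacer <- random_dna(1, gaps[i])
      pieces[2 * i - 1] <- spacer
      pos <- pos + gaps[i]
      starts[i] <- pos
      pieces[2 * i] <- feat$seq[i]
      pos <- pos + widths[i]
    }
    pieces[2 * nrow(feat) + 1] <- random_dna(1, gaps[nrow(feat) + 1])
    chrom <- paste(pieces, collapse = "")

    features <- tibble(category = feat$category, name = feat$name,
                       seq_id = "ref_1", start = starts,
                       end = starts + widths - 1L, strand = "+")
    features <- arrange(features, .data$start)
    reference_bundle(
      Biostrings::DNAStringSet(setNames(chrom, "ref_1")), features)
  })
}

#' Construct a reference bundle
#'
#' @param sequences a [Biostrings::DNAStringSet] of reference sequences.
#' @param features tibble with columns `category`, `name`, `seq_id`,
#'   `start`, `end`, `strand` (1-based closed coordinates).
#' @return an object of class `reference_bundle`.
#' @export
reference_bundle <- function(sequences, features) {
  features <- as_tibble(features)
  req <- c("category", "name", "seq_id", "start", "end", "strand")
  stopifnot(all(req %in% names(features)))
  bad <- setdiff(unique(features$category), CATEGORY_PRIORITY)
  if (length(bad)) {
    abort(sprintf("Unknown feature categories: %s.", paste(bad, collapse = ", ")))
  }
  if (!all(features$seq_id %in% names(sequences))) {
    abort("Every feature must lie on a named reference sequence.")
  }
  lens <- setNames(Biostrings::width(sequences), names(sequences))
  if (any(features$start < 1 | features$end > lens[features$seq_id])) {
    abort("Feature intervals must lie within their reference sequence.")
  }
  mir <- features$name[features$category == "miRNA"]
  if (anyDuplicated(mir)) abort("miRNA feature names must be unique.")
  structure(list(sequences = sequences, features = features),
            class = "reference_bundle")
}

#' @export
print.reference_bundle <- function(x, ...) {
  cat(sprintf("<reference_bundle> %d sequence(s) (%d bp), %d features (%d miRNA)\n",
              length(x$sequences), sum(Biostrings::width(x$sequences)),
              nrow(x$features), sum(x$features$category == "miRNA")))
  invisible(x)
}

# Extract feature sequences (respecting strand) as a character vector
# parallel to ref$features rows.
feature_sequences <- function(ref) {
  chrom <- setNames(as.character(ref$sequences), names(ref$sequences))
  seqs <- substring(chrom[ref$features$seq_id], ref$features$start,
                    ref$features$end)
  minus <- ref$features$strand == "-"
  if (any(minus)) {
    seqs[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[minus])))
  }
  unname(seqs)
}

#' Named mature-miRNA sequences of a reference
#'
#' @param ref a `reference_bundle`.
#' @return named character vector, one element per miRNA feature.
#' @export
mirna_sequences <- function(ref) {
  seqs <- feature_sequences(ref)
  keep <- ref$features$category == "miRNA"
  setNames(seqs[keep], ref$features$name[keep])
}

#' Dosage-weighted true proportions for a hybrid
#'
#' Composes the true miRNA proportion vector of a hybrid from its parental
#' vectors: the dosage-weighted mean of the parental proportions, times
#' `2^effect` for miRNAs carrying a planted non-additive effect, then
#' renormalized to sum to 1. With no planted effects this is exactly the
#' mid-parent expectation, e.g. (PP+AA)/2 for a PA diploid and (PP+2AA)/3
#' for a PAA triploid.
#'
#' @param truth a [simulation_truth()].
#' @param composition a [genome_composition()] giving the parental dosages.
#' @param hybrid_label which entry of `truth$nonadditive_set` to apply;
#'   defaults to the composition label.
#' @return named numeric vector of true proportions summing to 1.
#' @export
compose_hybrid_truth <- function(truth, composition,
                                 hybrid_label = NULL) {
  composition <- genome_composition(composition)
  hybrid_label <- hybrid_label %||% composition$label
  dosage <- composition$dosage[composition$dosage > 0]
  missing <- setdiff(names(dosage), names(truth$parental_proportions))
  if (length(missing)) {
    abort(sprintf("No parental proportions for genome(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "polymir_missing_parent")
  }
  v <- Reduce(`+`, lapply(names(dosage), function(g) {
    dosage[[g]] * truth$parental_proportions[[g]]
  })) / sum(dosage)
  eff <- truth$nonadditive_set[[hybrid_label]]
  if (!is.null(eff) && length(eff)) {
    v[names(eff)] <- v[names(eff)] * 2^eff
  }
  v / sum(v)
}

#' Recurrent contaminant fragments of a reference
#'
#' Degradation products of structural RNAs, repeats and mRNA fragments are
#' not uniform substrings: libraries re-sequence the same preferred
#' fragments over and over. This pool of weighted (feature, start, length)
#' fragments models those recurrent products. It is a property of the
#' reference — derived deterministically from it with a fixed internal
#' seed — so all libraries simulated on the same reference share the same
#' pool, which is what makes most of their unique sequences common.
#'
#' @param ref a `reference_bundle` with non-miRNA features.
#' @param fragments_per_kb pool density over the contaminant feature span.
#' @param length_model fragment length distribution over 14--30 nt.
#' @param seed pool seed; fixed by default so the pool is a pure function
#'   of the reference.
#' @return tibble with columns `seq`, `category`, `weight`.
#' @export
contaminant_fragment_pool <- function(ref, fragments_per_kb = 450,
                                      length_model = default_length_model(),
                                      seed = 93L) {
  is_contam <- ref$features$category != "miRNA"
  if (!any(is_contam)) abort("Reference has no contaminant features.")
  fseq <- feature_sequences(ref)[is_contam]
  fcat <- ref$features$category[is_contam]
  w <- nchar(fseq)
  n_frag <- max(1L, as.integer(round(sum(w) / 1000 * fragments_per_kb)))
  with_seed(seed, {
    idx <- sample.int(length(fseq), n_frag, replace = TRUE,
                      prob = w / sum(w))
    L <- as.integer(sample(14:30, n_frag, replace = TRUE,
                           prob = length_model))
    L <- pmin(L, w[idx])
    start <- floor(runif(n_frag) * (w[idx] - L + 1)) + 1L
    tibble(seq = substring(fseq[idx], start, start + L - 1L),
           category = fcat[idx],
           weight = rlnorm(n_frag, meanlog = 0, sdlog = 0.5))
  })
}

#' Simulate one small-RNA library
#'
#' Draws `n_reads` reads: a binomial share of contaminant reads and miRNA
#' reads drawn multinomially from `true_proportions`, each an exact or
#' slightly 3'-truncated copy of its mature-miRNA feature sequence. Most
#' contaminant reads come from the reference's recurrent fragment pool
#' ([contaminant_fragment_pool()]), shared by every library on that
#' reference; a small `private_rate` of them are uniform random substrings
#' of contaminant features, the library-specific tail of rare sequences.
#' Deterministic given `seed`.
#'
#' @param true_proportions named numeric vector over the reference's miRNA
#'   features, summing to 1 within 1e-6.
#' @param reference a `reference_bundle`.
#' @param n_reads total number of reads (>= 1).
#' @param contaminant_fraction expected fraction of contaminant reads.
#' @param length_model probability vector over lengths 14--30 for
#'   contaminant reads.
#' @param seed RNG seed.
#' @param label,composition passed to [tag_library()].
#' @param truncation_probs probabilities that a miRNA read is 3'-truncated
#'   by 0, 1, 2 or 3 nt (imprecise processing / degradation).
#' @param fragment_pool recurrent contaminant fragments; defaults to
#'   [contaminant_fragment_pool()] of the reference.
#' @param private_rate fraction of contaminant reads drawn as uniform
#'   random substrings instead of pool fragments.
#'
#' @return a `tag_library`; attribute `simulated_truth` records the drawn
#'   per-miRNA read counts and per-category contaminant read counts.
#' @export
simulate_library <- function(true_proportions, reference, n_reads,
                             contaminant_fraction = 0,
                             length_model = default_length_model(),
                             seed = NULL, label = "sim",
                             composition = NULL,
                             truncation_probs = c(0.92, 0.05, 0.02, 0.01),
                             fragment_pool = NULL,
                             private_rate = 0.0065) {
  assert_positive_int(n_reads, "n_reads")
  if (abs(sum(true_proportions) - 1) > 1e-6) {
    abort("`true_proportions` must sum to 1.")
  }
  mir_seq <- mirna_sequences(reference)
  if (!all(names(true_proportions) %in% names(mir_seq))) {
    abort("`true_proportions` names must match reference miRNA features.")
  }
  with_seed(seed, {
    n_contam <- rbinom(1, n_reads, contaminant_fraction)
    n_mir <- n_reads - n_contam

    tag_rows <- list()
    mir_counts <- setNames(integer(length(true_proportions)),
                           names(true_proportions))
    if (n_mir > 0) {
      cnt <- rmultinom(1, n_mir, true_proportions)[, 1]
      mir_counts <- cnt
      nz <- names(cnt)[cnt > 0]
      if (length(nz)) {
        rows <- lapply(nz, function(m) {
          L <- nchar(mir_seq[[m]])
          ks <- 0:3
          ks <- ks[L - ks >= 14]
          pk <- truncation_probs[seq_along(ks)]
          split <- rmultinom(1, cnt[[m]], pk / sum(pk))[, 1]
          keep <- split > 0
          tibble(seq = substr(rep(mir_seq[[m]], sum(keep)), 1,
                              L - ks[keep]),
                 count = split[keep])
        })
        tag_rows <- c(tag_rows, rows)
      }
    }

    contam_by_cat <- integer(0)
    if (n_contam > 0) {
      is_contam <- reference$features$category != "miRNA"
      if (!any(is_contam)) {
        abort("contaminant_fraction > 0 requires contaminant features in the reference.")
      }
      pool <- fragment_pool %||%
        contaminant_fragment_pool(reference, length_model = length_model)
      n_private <- rbinom(1, n_contam, private_rate)
      n_pool <- n_contam - n_private
      reads <- character(0)
      cats <- character(0)
      if (n_pool > 0) {
        pick <- sample.int(nrow(pool), n_pool, replace = TRUE,
                           prob = pool$weight)
        reads <- pool$seq[pick]
        cats <- pool$category[pick]
      }
      if (n_private > 0) {
        fseq <- feature_sequences(reference)[is_contam]
        fcat <- reference$features$category[is_contam]
        w <- nchar(fseq)
        idx <- sample.int(length(fseq), n_private, replace = TRUE,
                          prob = w / sum(w))
        L <- as.integer(sample(14:30, n_private, replace = TRUE,
                               prob = length_model))
        L <- pmin(L, w[idx])
        start <- floor(runif(n_private) * (w[idx] - L + 1)) + 1L
        reads <- c(reads, substring(fseq[idx], start, start + L - 1L))
        cats <- c(cats, fcat[idx])
      }
      contam_by_cat <- c(table(cats))
      ct <- table(reads)
      tag_rows <- c(tag_rows, list(tibble(seq = names(ct),
                                          count = as.integer(ct))))
    }

    tags <- bind_rows(tag_rows) %>%
      group_by(.data$seq) %>%
      summarise(count = sum(.data$count), .groups = "drop")
    lib <- tag_library(tags, label = label, composition = composition)
    attr(lib, "simulated_truth") <- list(
      mirna_counts = mir_counts,
      contaminant_counts_by_category = contam_by_cat,
      n_reads = n_reads)
    lib
  })
}

#' Multinomial miRNA read counts from true proportions
#'
#' Count-level shortcut past read simulation: draws per-miRNA read counts
#' directly. Used for large replicate studies (calibration, power) where
#' sequence-level detail is irrelevant.
#'
#' @param true_proportions named numeric proportions summing to 1.
#' @param n_reads total miRNA reads.
#' @param seed RNG seed.
#' @return named integer vector of counts summing to `n_reads`.
#' @export
simulate_mirna_counts <- function(true_proportions, n_reads, seed = NULL) {
  assert_positive_int(n_reads, "n_reads")
  with_seed(seed, {
    rmultinom(1, n_reads, true_proportions)[, 1]
  })
}

#' Simulate a full four-library study
#'
#' Generates the default study design of the package: two non-hybrid
#' parental forms (PP = P:2, AA = A:2), the diploid hybrid PA (P:1,A:1) and
#' the triploid hybrid PAA (P:1,A:2). Hybrid true profiles are additive
#' dosage-weighted mixtures of the parental profiles, except for a
#' controllable non-additive subset (by default 30% of miRNAs up-shifted by
#' one log2 unit in the triploid, emulating the over-expression response to
#' ploidy increase).
#'
#' @param n_mirnas number of miRNAs in the reference (default 204, the size
#'   of a conserved miRNA set shared by all libraries).
#' @param n_reads reads per library.
#' @param n_contaminant_features non-miRNA features in the reference.
#' @param contaminant_fraction expected contaminant read fraction.
#' @param nonadditive named list per hybrid label with elements `fraction`
#'   and `log2_effect`, or a precomputed `nonadditive_set` style list of
#'   named effect vectors.
#' @param seed RNG seed (split deterministically across libraries).
#' @return list with `reference`, `truth` (a `simulation_truth`),
#'   `true_proportions` (per library) and `libraries` (named list of
#'   `tag_library`).
#' @export
simulate_study <- function(n_mirnas = 204, n_reads = 2e5,
                           n_contaminant_features = 15,
                           contaminant_fraction = 0.15,
                           nonadditive = list(PAA = list(fraction = 0.3,
                                                         log2_effect = 1)),
                           seed = NULL) {
  reference <- simulate_reference(n_mirnas, n_contaminant_features,
                                  seed = child_seed(seed, 1))
  mirnas <- reference$features$name[reference$features$category == "miRNA"]
  props <- random_parental_proportions(mirnas, c("P", "A"),
                                       seed = child_seed(seed, 2))
  nonadd <- with_seed(child_seed(seed, 3), {
    lapply(nonadditive, function(spec) {
      if (is.numeric(spec)) return(spec)  # already a named effect vector
      k <- round(spec$fraction * length(mirnas))
      setNames(rep(spec$log2_effect, k), sample(mirnas, k))
    })
  })
  truth <- simulation_truth(mirnas, props, nonadditive_set = nonadd,
                            contaminant_fraction = contaminant_fraction)
  comps <- list(PP = genome_composition(c(P = 2), "PP"),
                AA = genome_composition(c(A = 2), "AA"),
                PA = genome_composition(c(P = 1, A = 1), "PA"),
                PAA = genome_composition(c(P = 1, A = 2), "PAA"))
  true_props <- lapply(names(comps), function(lbl) {
    compose_hybrid_truth(truth, comps[[lbl]], hybrid_label = lbl)
  })
  names(true_props) <- names(comps)
  libraries <- lapply(seq_along(comps), function(i) {
    lbl <- names(comps)[i]
    simulate_library(true_props[[lbl]], reference, n_reads,
                     contaminant_fraction = contaminant_fraction,
                     length_model = truth$length_model,
                     seed = child_seed(seed, 10 + i),
                     label = lbl, composition = comps[[lbl]])
  })
  names(libraries) <- names(comps)
  list(reference = reference, truth = truth,
       true_proportions = true_props, libraries = libraries)
}
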