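#' Default run manifest for a simulated four-library study
#'
#' Builds the manifest describing the package's default study design: two
#' non-hybrid diploids (PP, AA), the diploid hybrid PA and the triploid
#' hybrid PAA, simulated at the given depth, with all analysis options at
#' their defaults.
#'
#' @param seed global RNG seed (split deterministically per stage).
#' @param n_mirnas,n_reads,n_contaminant_features,contaminant_fraction
#'   simulation scale; see [simulate_study()].
#' @param nonadditive planted non-additive subsets per hybrid; see
#'   [simulate_study()].
#' @return a manifest list, ready for [run_pipeline()].
#' @export
default_manifest <- function(seed = 1, n_mirnas = 204, n_reads = 2e5,
                             n_contaminant_features = 15,
                             contaminant_fraction = 0.15,
                             nonadditive = list(PAA = list(fraction = 0.3,
                                                           log2_effect = 1))) {
  list(
    seed = seed,
    reference = list(n_mirnas = n_mirnas,
                     n_contaminant_features = n_contaminant_features),
    libraries = list(
      list(label = "PP", composition = "P:2", n_reads = n_reads),
      list(label = "AA", composition = "A:2", n_reads = n_reads),
      list(label = "PA", composition = "P:1,A:1", n_reads = n_reads),
      list(label = "PAA", composition = "P:1,A:2", n_reads = n_reads)),
    options = list(contaminant_fraction = contaminant_fraction,
                   pseudocount = NULL, band = 1, cutoff = 1,
                   universe = "intersection",
                   adapter = "", min_len = 14, max_len = 30,
                   min_mean_quality = 20,
                   nonadditive = nonadditive))
}

#' Read a run manifest from YAML
#'
#' @param path YAML manifest path.
#' @return manifest list.
#' @export
read_manifest <- function(path) {
  yaml::read_yaml(path)
}

#' Validate a run manifest
#'
#' Checks every manifest invariant at once: unique labels, well-formed
#' dosages, a simulation block or input file per library, readable paths,
#' and — for every hybrid composition — exactly one non-hybrid library per
#' parental genome symbol (needed for the additivity expectation).
#'
#' @param manifest manifest list (see [default_manifest()]).
#' @return tibble of violations with columns `field` and `problem`; zero
#'   rows means the manifest is valid.
#' @export
validate_manifest <- function(manifest) {
  probs <- list()
  add <- function(field, problem) {
    probs[[length(probs) + 1]] <<- tibble(field = field, problem = problem)
  }
  libs <- manifest$libraries
  if (is.null(libs) || length(libs) < 1) {
    add("libraries", "no libraries declared")
    return(bind_rows(probs))
  }
  labels <- vapply(libs, function(l) l$label %||% NA_character_,
                   character(1))
  if (any(is.na(labels))) add("libraries", "every library needs a label")
  dup <- unique(labels[duplicated(labels)])
  if (length(dup)) add("libraries",
                       sprintf("duplicate label(s): %s",
                               paste(dup, collapse = ", ")))
  comps <- vector("list", length(libs))
  for (i in seq_along(libs)) {
    l <- libs[[i]]
    comps[[i]] <- tryCatch(genome_composition(l$composition),
                           error = function(e) {
      add(sprintf("libraries[%d]", i),
          sprintf("invalid dosage for '%s': %s", l$label %||% i,
                  conditionMessage(e)))
      NULL
    })
    has_sim <- !is.null(l$n_reads)
    has_file <- !is.null(l$fastq) || !is.null(l$collapsed_fasta)
    if (!has_sim && !has_file) {
      add(sprintf("libraries[%d]", i),
          sprintf("'%s' has neither simulation parameters nor input files",
                  l$label %||% i))
    }
    for (f in c(l$fastq, l$collapsed_fasta)) {
      if (!file.exists(f)) {
        add(sprintf("libraries[%d]", i),
            sprintf("input file not readable: %s", f))
      }
    }
  }
  ok <- !vapply(comps, is.null, logical(1))
  if (any(ok)) {
    pure_of <- list()
    for (i in which(ok)) {
      if (is_pure(comps[[i]])) {
        sym <- names(comps[[i]]$dosage)[comps[[i]]$dosage > 0]
        pure_of[[sym]] <- c(pure_of[[sym]], labels[i])
      }
    }
    hybrid_syms <- unique(unlist(lapply(comps[ok], function(cc) {
      if (!is_pure(cc)) names(cc$dosage)[cc$dosage > 0]
    })))
    for (sym in hybrid_syms) {
      n_pure <- length(pure_of[[sym]] %||% character(0))
      if (n_pure == 0) {
        add("libraries",
            sprintf("no non-hybrid library provides parental genome '%s'",
                    sym))
      } else if (n_pure > 1) {
        add("libraries",
            sprintf("parental genome '%s' provided by several libraries: %s",
                    sym, paste(pure_of[[sym]], collapse = ", ")))
      }
    }
  }
  if (!is.null(manifest$reference)) {
    r <- manifest$reference
    sim_ref <- !is.null(r$n_mirnas)
    file_ref <- !is.null(r$fasta) && !is.null(r$features)
    if (!sim_ref && !file_ref) {
      add("reference", "needs either n_mirnas or fasta+features paths")
    }
    if (file_ref) {
      for (f in c(r$fasta, r$features)) {
        if (!file.exists(f)) add("reference",
                                 sprintf("file not readable: %s", f))
      }
    }
  } else {
    add("reference", "no reference block")
  }
  opt <- manifest$options %||% list()
  if (!is.null(opt$band) && (!is.numeric(opt$band) || opt$band <= 0)) {
    add("options", "band must be a positive number")
  }
  if (!is.null(opt$pseudocount) && opt$pseudocount < 0) {
    add("options", "pseudocount must be non-negative")
  }
  bind_rows(probs)
}

# Canonical comparison order: total dosage desc, number of distinct
# genomes desc, then label — puts the triploid hybrid first, hybrids
# before non-hybrids (PAA, PA, AA, PP in the default design).
comparison_order <- function(labels, comps) {
  td <- vapply(comps, total_dosage, numeric(1))
  ng <- vapply(comps, function(cc) sum(cc$dosage > 0), numeric(1))
  labels[order(-td, -ng, labels)]
}

#' Run the full small-RNA comparison pipeline
#'
#' Executes every stage in dependency order: reference acquisition,
#' library simulation or loading, tag collapsing, pairwise shared-sequence
#' comparison, mapping and hierarchical annotation, miRNA expression
#' profiles and matrix, all pairwise crescent-curve comparisons with
#' fold-change bins and cross-comparison consistency, and the additivity
#' analysis of every hybrid against its dosage-weighted mid-parent
#' expectation. All tables are written as TSV under `outdir`; outputs are
#' deterministic given the manifest and its seed.
#'
#' @param manifest manifest list (see [default_manifest()],
#'   [read_manifest()]); validated first, aborting with every problem
#'   listed.
#' @param outdir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return a run report: list with per-stage parameters, output paths and
#'   headline statistics, also written to `run_report.json`.
#' @export
run_pipeline <- function(manifest, outdir = tempfile("polymir_run_"),
                         quiet = FALSE) {
  problems <- validate_manifest(manifest)
  if (nrow(problems)) {
    abort(paste0("Invalid manifest:\n", paste0("- [", problems$field, "] ",
                 problems$problem, collapse = "\n")),
          class = "polymir_invalid_manifest")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  seed <- manifest$seed %||% NULL
  opt <- manifest$options %||% list()
  band <- opt$band %||% 1
  cutoff <- opt$cutoff %||% 1
  outputs <- character(0)
  out_path <- function(...) {
    p <- file.path(outdir, paste0(...))
    outputs <<- c(outputs, p)
    p
  }

  ## -- reference ---------------------------------------------------------
  r <- manifest$reference
  if (!is.null(r$n_mirnas)) {
    say("reference", "simulating %d miRNA + %d contaminant features",
        r$n_mirnas, r$n_contaminant_features %||% 0)
    reference <- simulate_reference(r$n_mirnas,
                                    r$n_contaminant_features %||% 0,
                                    seed = child_seed(seed, 1))
  } else {
    say("reference", "reading %s / %s", r$fasta, r$features)
    reference <- read_reference(r$fasta, r$features)
  }
  write_reference(reference, out_path("reference.fasta"),
                  out_path("reference.gff3"))
  mirnas <- reference$features$name[reference$features$category == "miRNA"]

  ## -- libraries ---------------------------------------------------------
  libs <- manifest$libraries
  labels <- vapply(libs, function(l) l$label, character(1))
  comps <- lapply(libs, function(l) genome_composition(l$composition))
  names(comps) <- labels
  need_sim <- vapply(libs, function(l) is.null(l$fastq) &&
                       is.null(l$collapsed_fasta), logical(1))
  truth <- NULL
  if (any(need_sim)) {
    symbols <- sort(unique(unlist(lapply(comps, function(cc)
      names(cc$dosage)[cc$dosage > 0]))))
    props <- random_parental_proportions(mirnas, symbols,
                                         seed = child_seed(seed, 2))
    nonadd <- with_seed(child_seed(seed, 3), {
      lapply(opt$nonadditive %||% list(), function(spec) {
        if (is.numeric(spec)) return(spec)
        k <- round(spec$fraction * length(mirnas))
        setNames(rep(spec$log2_effect, k), sample(mirnas, k))
      })
    })
    truth <- simulation_truth(mirnas, props, nonadditive_set = nonadd,
                              contaminant_fraction =
                                opt$contaminant_fraction %||% 0.15)
  }
  tag_libs <- vector("list", length(libs))
  filter_rows <- list()
  for (i in seq_along(libs)) {
    l <- libs[[i]]
    if (need_sim[i]) {
      say("process", "simulating library %s (%d reads)", l$label, l$n_reads)
      tp <- compose_hybrid_truth(truth, comps[[i]], hybrid_label = l$label)
      tag_libs[[i]] <- simulate_library(
        tp, reference, l$n_reads,
        contaminant_fraction = truth$contaminant_fraction,
        length_model = truth$length_model,
        seed = child_seed(seed, 10 + i),
        label = l$label, composition = comps[[i]])
    } else if (!is.null(l$fastq)) {
      say("process", "filtering and collapsing %s", l$fastq)
      kept <- filter_reads(read_fastq(l$fastq),
                           adapter = opt$adapter %||% "",
                           min_len = opt$min_len %||% 14,
                           max_len = opt$max_len %||% 30,
                           min_mean_quality = opt$min_mean_quality %||% 20)
      filter_rows[[l$label]] <- mutate(filter_report(kept),
                                       library = l$label, .before = 1)
      tag_libs[[i]] <- collapse_tags(kept, label = l$label,
                                     composition = comps[[i]])
    } else {
      say("process", "reading collapsed tags %s", l$collapsed_fasta)
      tag_libs[[i]] <- read_collapsed_fasta(l$collapsed_fasta,
                                            label = l$label,
                                            composition = comps[[i]])
    }
    write_collapsed_fasta(tag_libs[[i]],
                          out_path("tags_", l$label, ".fasta"))
  }
  names(tag_libs) <- labels
  if (length(filter_rows)) {
    write_tsv_plain(bind_rows(filter_rows), out_path("filter_report.tsv"))
  }

  ## -- pairwise shared sequences ----------------------------------------
  say("compare-tags", "pairwise shared sequences over %d libraries",
      length(tag_libs))
  shared <- shared_matrix(tag_libs)
  write_tsv_plain(shared, out_path("shared_sequences.tsv"))
  write_tsv_plain(shared_library_summary(shared),
                  out_path("shared_library_summary.tsv"))

  ## -- annotation --------------------------------------------------------
  annotated <- lapply(tag_libs, function(lb) {
    say("annotate", "mapping and annotating %s", lib_label(lb))
    annotate_tags(map_tags(lb, reference), reference)
  })
  cat_rows <- bind_rows(lapply(annotated, function(a) {
    mutate(category_summary(a), library = lib_label(a), .before = 1)
  }))
  write_tsv_plain(cat_rows, out_path("category_summary.tsv"))
  for (a in annotated) {
    write_tsv_plain(a, out_path("annotation_", lib_label(a), ".tsv"))
  }

  ## -- expression --------------------------------------------------------
  say("express", "miRNA expression profiles")
  profiles <- lapply(annotated, mirna_expression)
  universe <- if (identical(opt$universe %||% "intersection", "union")) {
    sort(unique(unlist(lapply(profiles, function(p) p$mirna))))
  } else NULL
  mat <- expression_matrix(profiles, universe = universe)
  mat_out <- mat
  for (lbl in labels) mat_out[[lbl]] <- signif(mat_out[[lbl]], 6)
  write_tsv_plain(mat_out, out_path("expression_matrix.tsv"))

  ## -- comparative stats -------------------------------------------------
  ord <- comparison_order(labels, comps)
  pairs <- utils::combn(ord, 2)
  depths <- vapply(profiles, total_mirna_reads, numeric(1))
  crescents <- list()
  fcs <- list()
  cor_rows <- list()
  bin_rows <- list()
  for (j in seq_len(ncol(pairs))) {
    lu <- pairs[1, j]; lv <- pairs[2, j]
    eps <- if (!is.null(opt$pseudocount)) opt$pseudocount else
      0.5 / min(depths[c(lu, lv)])
    fc <- fold_changes_vec(matrix_column(mat, lu), matrix_column(mat, lv),
                           pseudocount = eps, labels = c(lu, lv))
    fcs[[paste0(lu, "/", lv)]] <- fc
    cs <- crescent_summary(fc)
    crescents[[cs$pair]] <- cs
    write_tsv_plain(tidy(cs), out_path("ratios_", lu, "_vs_", lv, ".tsv"))
    cor_rows[[j]] <- tibble(library_a = lu, library_b = lv,
                            pearson_r = profile_correlation(
                              profiles[[lu]], profiles[[lv]]))
    bin_rows[[j]] <- mutate(fold_change_bins(fc), pair = cs$pair,
                            .before = 1)
  }
  say("crescent", "%d pairwise comparisons", length(crescents))
  write_tsv_plain(bind_rows(lapply(crescents, glance)),
                  out_path("crescent_summary.tsv"))
  write_tsv_plain(bind_rows(cor_rows), out_path("correlations.tsv"))
  write_tsv_plain(bind_rows(bin_rows), out_path("fold_change_bins.tsv"))

  consistency <- NULL
  first <- ord[1]
  first_pairs <- names(fcs)[startsWith(names(fcs), paste0(first, "/"))]
  if (length(first_pairs) >= 2) {
    consistency <- consistency_across(fcs[[first_pairs[1]]],
                                      fcs[first_pairs[-1]],
                                      cutoff = NULL)
    write_tsv_plain(mutate(consistency, primary = first_pairs[1],
                           .before = 1),
                    out_path("consistency.tsv"))
  }

  ## -- additivity --------------------------------------------------------
  pure_lbl <- labels[vapply(comps, is_pure, logical(1))]
  parents <- lapply(pure_lbl, function(lbl) profiles[[lbl]])
  names(parents) <- vapply(pure_lbl, function(lbl) {
    names(comps[[lbl]]$dosage)[comps[[lbl]]$dosage > 0]
  }, character(1))
  hybrids <- labels[!vapply(comps, is_pure, logical(1))]
  add_results <- list()
  for (h in hybrids) {
    say("additivity", "hybrid %s vs dosage expectation", h)
    expd <- expected_profile(parents, comps[[h]], universe = mat$mirna)
    obs <- profiles[[h]]
    eps <- if (!is.null(opt$pseudocount)) opt$pseudocount else
      0.5 / min(depths)
    res <- additivity_deviation(obs, expd, band = band, pseudocount = eps)
    add_results[[h]] <- res
    write_tsv_plain(tidy(res), out_path("additivity_", h, ".tsv"))
  }
  if (length(add_results)) {
    write_tsv_plain(additivity_report(add_results),
                    out_path("additivity_summary.tsv"))
  }

  ## -- report ------------------------------------------------------------
  report <- list(
    package_version = as.character(utils::packageVersion("polymir")),
    seed = seed,
    manifest = manifest,
    outdir = outdir,
    outputs = basename(outputs),
    libraries = lapply(tag_libs, function(lb) {
      list(label = lib_label(lb), total_reads = total_reads(lb),
           total_unique = total_unique(lb))
    }),
    mapped_fraction = lapply(annotated, function(a)
      attr(a, "mapped_fraction")),
    universe_size = nrow(mat),
    mean_shared_pct = mean(shared$shared_pct_mean),
    crescent = lapply(crescents, function(cs)
      as.list(glance(cs))),
    consistency = if (!is.null(consistency))
      as.list(consistency[consistency$direction == "up",
                          c("n_primary", "frac_any", "frac_all")][1, ]),
    additivity = lapply(add_results, function(res) as.list(glance(res))))
  json_path <- out_path("run_report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  say("done", "outputs in %s", outdir)
  invisible(report)
}
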