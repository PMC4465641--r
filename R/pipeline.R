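#' Scan proteomics peptide tables for protein-level splice evidence
#'
#' The package's main entry point. Runs the full analysis: per-dataset
#' quality filtering (enzyme specificity, score and search-engine rules,
#' missed-cleavage support), cross-experiment replication, I/L-insensitive
#' peptide-to-isoform mapping, main-isoform selection, splice-event
#' extraction and classification between the main isoform and every
#' alternative, detection of events with peptide evidence on both sides
#' (ISEs), and — when domain annotations are supplied — domain-impact
#' tallies.
#'
#' Read-through isoforms are excluded before mapping; gene clusters, when
#' given, are merged into single genes first.
#'
#' @param gs a [gene_set()].
#' @param peptide_tables named list (by dataset id) of peptide record
#'   data.frames (see [read_peptide_table()]).
#' @param dataset_configs named list of [dataset_filter_config()]; default
#'   builds a permissive config per dataset.
#' @param clusters optional cluster definitions for
#'   [merge_gene_clusters()].
#' @param principal_table optional principal-isoform table.
#' @param min_datasets cross-experiment replication threshold.
#' @param min_len minimum sub-peptide length for missed-cleavage support.
#' @param domain_annotations optional per-isoform domain table.
#' @param break_overrides domain accessions exempt from the
#'   homologous-substitution "unbroken" rule.
#' @param homology_seed seed for the homology-test shuffles.
#' @param evidence_threshold peptides per gene needed to call a gene
#'   detected.
#' @return An object of class `splice_scan`; see [summary.splice_scan()].
#' @export
splice_scan <- function(gs, peptide_tables, dataset_configs = NULL,
                        clusters = NULL, principal_table = NULL,
                        min_datasets = 2L, min_len = 7L,
                        domain_annotations = NULL,
                        break_overrides = character(),
                        homology_seed = 1L, evidence_threshold = 2L) {
  if (!is.null(clusters)) gs <- merge_gene_clusters(gs, clusters)
  if (any(gs$isoforms$read_through))
    gs <- subset_isoforms(gs,
                          gs$isoforms$isoform_id[!gs$isoforms$read_through])
  gs <- mark_principal(gs, principal_table)

  if (is.null(dataset_configs))
    dataset_configs <- lapply(names(peptide_tables), dataset_filter_config)
  if (is.null(names(dataset_configs)) || !all(nzchar(names(dataset_configs))))
    names(dataset_configs) <- vapply(dataset_configs, `[[`, "", "dataset_id")

  filtered <- lapply(names(peptide_tables), function(ds) {
    cfg <- dataset_configs[[ds]] %||% dataset_filter_config(ds)
    fp <- apply_dataset_filters(peptide_tables[[ds]], cfg)
    enforce_missed_cleavage_support(fp, min_len = min_len)
  })
  names(filtered) <- names(peptide_tables)

  peptides <- cross_experiment_filter(filtered, min_datasets = min_datasets)
  matches <- map_peptides(peptides, gs)
  evidence <- count_gene_evidence(matches, threshold = evidence_threshold)

  main_iso <- character(); events <- list(); ises <- list()
  genes_with_matches <- unique(matches$gene_id)
  for (g in genes_with_matches) {
    ids <- gs_isoforms_of(gs, g)
    if (length(ids) < 2L) next
    main <- pick_main_isoform(gs, g, matches)
    main_iso[g] <- main
    for (alt in setdiff(ids, main)) {
      evs <- extract_events(gs, main, alt)
      evs <- classify_events(evs, seed = homology_seed)
      for (ev in evs) {
        events[[length(events) + 1L]] <- ev
        hit <- detect_ise(ev, matches)
        if (!is.null(hit)) ises[[length(ises) + 1L]] <- hit
      }
    }
  }
  events <- dedupe_events(events)
  ise_events <- dedupe_events(lapply(ises, `[[`, "event"))
  ise_keys <- vapply(ise_events, function(e)
    paste(e$gene_id, e$kind, e$genomic_key, sep = "\r"), character(1))
  all_keys <- vapply(lapply(ises, `[[`, "event"), function(e)
    paste(e$gene_id, e$kind, e$genomic_key, sep = "\r"), character(1))
  ises <- ises[match(ise_keys, all_keys)]

  domain_tally <- if (!is.null(domain_annotations) && length(ise_events))
    tally_domain_effects(ise_events, domain_annotations, break_overrides)
  else NULL

  kinds <- vapply(ise_events, `[[`, "", "kind")
  kind_levels <- c("indel", "nagnag", "homologous_substitution",
                   "cterm_substitution", "nterm_substitution",
                   "internal_substitution", "two_proteins")
  ise_kind_counts <- vapply(kind_levels, function(k) sum(kinds == k),
                            integer(1))

  disc <- unique(as.data.frame(matches)[, c("canon_seq",
                                            "isoform_discriminating")])
  structure(list(
    gene_set = gs,
    filtered = filtered,
    peptides = peptides,
    matches = matches,
    evidence = evidence,
    main_isoforms = main_iso,
    events = events,
    ises = ises,
    ise_events = ise_events,
    ise_kind_counts = ise_kind_counts,
    domain_tally = domain_tally,
    as_genes = unique(vapply(ise_events, `[[`, "", "gene_id")),
    n_genes_detected = sum(evidence$detected),
    n_peptides_mapped = nrow(disc),
    n_discriminating = sum(disc$isoform_discriminating),
    min_datasets = min_datasets,
    evidence_threshold = evidence_threshold), class = "splice_scan")
}

#' @export
print.splice_scan <- function(x, ...) {
  cat("splice_scan: protein-level alternative splicing evidence\n")
  cat(sprintf("  peptides after cross-experiment filter: %d\n",
              nrow(x$peptides)))
  cat(sprintf("  genes detected (>=%d peptides): %d\n",
              x$evidence_threshold, x$n_genes_detected))
  cat(sprintf("  identified splicing events (ISEs): %d in %d genes\n",
              length(x$ise_events), length(x$as_genes)))
  invisible(x)
}

#' Summarize a splice_scan
#'
#' @param object a `splice_scan`.
#' @param ... unused.
#' @return A `summary.splice_scan` list: filtering audits, mapping and
#'   discrimination counts, ISE counts and percentages per kind, AS gene
#'   count and the domain-impact tally when available.
#' @export
summary.splice_scan <- function(object, ...) {
  audits <- lapply(object$filtered, `[[`, "audit")
  pct <- if (sum(object$ise_kind_counts) > 0)
    count_percentages(object$ise_kind_counts) else object$ise_kind_counts
  out <- list(
    audits = audits,
    n_peptides = nrow(object$peptides),
    n_peptides_mapped = object$n_peptides_mapped,
    n_discriminating = object$n_discriminating,
    pct_discriminating = if (object$n_peptides_mapped > 0)
      100 * object$n_discriminating / object$n_peptides_mapped else NA_real_,
    n_genes_detected = object$n_genes_detected,
    n_ise = length(object$ise_events),
    n_as_genes = length(object$as_genes),
    ise_kind_counts = object$ise_kind_counts,
    ise_kind_percentages = pct,
    domain_tally = object$domain_tally)
  class(out) <- "summary.splice_scan"
  out
}

#' @export
print.summary.splice_scan <- function(x, ...) {
  cat("Peptide-level splice evidence summary\n")
  cat(sprintf("  high-confidence peptides:      %d\n", x$n_peptides))
  cat(sprintf("  gene-discriminating peptides:  %d (%.1f%% isoform-discriminating)\n",
              x$n_peptides_mapped, x$pct_discriminating))
  cat(sprintf("  genes detected:                %d\n", x$n_genes_detected))
  cat(sprintf("  AS genes / ISEs:               %d / %d\n",
              x$n_as_genes, x$n_ise))
  if (x$n_ise > 0) {
    cat("  ISEs by kind:\n")
    for (k in names(x$ise_kind_counts))
      if (x$ise_kind_counts[[k]] > 0)
        cat(sprintf("    %-26s %4d (%.1f%%)\n", k, x$ise_kind_counts[[k]],
                    x$ise_kind_percentages[[k]]))
  }
  if (!is.null(x$domain_tally)) {
    cat("  domain impact of ISEs: ")
    cat(paste(sprintf("%s=%d", names(x$domain_tally$counts),
                      x$domain_tally$counts), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Plot event-kind composition of a splice_scan
#'
#' @param x a `splice_scan`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.splice_scan <- function(x, ...) {
  counts <- x$ise_kind_counts
  if (sum(counts) == 0) {
    warning("no ISEs to plot", call. = FALSE)
    return(invisible(NULL))
  }
  graphics::barplot(count_percentages(counts),
                    names.arg = sub("_substitution", "", names(counts)),
                    las = 2, ylab = "% of identified splicing events", ...)
  invisible(NULL)
}

#' Simulate expected AS detection under null abundance models
#'
#' Runs the in-silico digestion null model against the observed per-gene
#' peptide counts of a fitted [splice_scan()]: builds the fully tryptic
#' unique-peptide database, draws per-gene peptide sets under the chosen
#' abundance model and scores both-sides AS evidence with the same rules
#' as the observed analysis. Also computes the tryptic-peptide-only
#' observed baseline for comparison.
#'
#' @param object a `splice_scan`.
#' @param nsim number of replicates.
#' @param seed RNG seed.
#' @param model `"uniform"` or `"dominant"`.
#' @param ratio dominance ratio for the dominant model.
#' @param db optional precomputed tryptic [build_peptide_db()].
#' @param ... unused.
#' @return list of class `splice_scan_sim` with elements `summary`
#'   (a `simulation_summary`), `observed` (tryptic-only observed AS-gene
#'   and three-plus counts) and `fold` (from [compare_to_observed()]).
#' @export
simulate.splice_scan <- function(object, nsim = 100L, seed = 1L,
                                 model = c("uniform", "dominant"),
                                 ratio = 50, db = NULL, ...) {
  model <- match.arg(model)
  gs <- object$gene_set
  if (is.null(db)) db <- build_peptide_db(gs)

  # observed baseline restricted to fully tryptic db peptides
  tryptic <- unique(db$canon_seq)
  m <- object$matches[object$matches$canon_seq %in% tryptic, , drop = FALSE]
  class(m) <- class(object$matches)
  obs_alts <- list()
  for (ise in object$ises) {
    ev <- ise$event
    hit <- detect_ise(ev, m)
    if (!is.null(hit))
      obs_alts[[ev$gene_id]] <- unique(c(obs_alts[[ev$gene_id]],
                                         ev$alt_isoform_id))
  }
  observed <- c(as_genes = length(obs_alts),
                three_plus_genes = sum(lengths(obs_alts) >= 2L))

  counts_df <- count_gene_evidence(m, threshold = 1L)
  per_gene <- stats::setNames(counts_df$n_peptides, counts_df$gene_id)

  summary <- simulate_draws(gs, db, per_gene, model = model, ratio = ratio,
                            replicates = nsim, seed = seed)
  structure(list(summary = summary, observed = observed,
                 fold = compare_to_observed(summary, as.list(observed))),
            class = "splice_scan_sim")
}

#' @export
print.splice_scan_sim <- function(x, ...) {
  print(x$summary)
  cat(sprintf("  observed (tryptic-only):  %d AS genes, %d with >=3 isoforms\n",
              x$observed[["as_genes"]], x$observed[["three_plus_genes"]]))
  cat(sprintf("  simulated / observed:     %.1f-fold (AS genes)\n",
              x$fold$as_gene_ratio))
  invisible(x)
}
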