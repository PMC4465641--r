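test_that("the generator is deterministic and writes byte-identical files", {
  s1 <- generate_gene_set(12L, seed = 5L)
  s2 <- generate_gene_set(12L, seed = 5L)
  expect_identical(s1, s2)
  d <- withr::local_tempdir()
  for (run in 1:2)
    write_gene_set(s1$gene_set, file.path(d, paste0("r", run, ".gtf")),
                   file.path(d, paste0("r", run, ".faa")))
  expect_identical(readLines(file.path(d, "r1.gtf")),
                   readLines(file.path(d, "r2.gtf")))
  expect_identical(readLines(file.path(d, "r1.faa")),
                   readLines(file.path(d, "r2.faa")))
  # a different seed changes the output
  expect_false(identical(generate_gene_set(12L, seed = 6L)$gene_set,
                         s1$gene_set))
})

test_that("planted proteins are consistent with their CDS and genome", {
  syn <- generate_gene_set(12L, seed = 5L)
  gs <- syn$gene_set
  for (id in gs$isoforms$isoform_id) {
    nt <- splicepep:::cds_nt_seq(gs, id, syn$genome)
    expect_identical(splicepep:::translate_cds(nt), gs_protein(gs, id))
    e <- gs$exons[gs$exons$isoform_id == id, ]
    expect_identical(sum(e$end - e$start) %% 3L, 0L)  # whole codons
  }
})

test_that("requesting a single event kind plants only that kind", {
  syn <- generate_gene_set(30L, seed = 17L,
                           event_props = c(indel = 1, nagnag = 0,
                                           homologous_substitution = 0,
                                           cterm_substitution = 0,
                                           nterm_substitution = 0,
                                           internal_substitution = 0,
                                           two_proteins = 0),
                           include_cluster = FALSE, n_readthrough = 0L,
                           n_par_decoys = 0L)
  expect_true(all(syn$truth$events$kind == "indel"))
  gs <- mark_principal(syn$gene_set)
  for (i in seq_len(nrow(syn$truth$events))) {
    tr <- syn$truth$events[i, ]
    evs <- splicepep:::classify_events(
      extract_events(gs, tr$main_isoform_id, tr$alt_isoform_id), seed = 1L)
    expect_length(evs, 1L)
    expect_identical(evs[[1]]$kind, "indel")
  }
})

test_that("event-kind allocation is an exact largest-remainder apportionment", {
  syn <- small_synth()
  ev <- syn$truth$events
  own <- ev[ev$gene_id != "UGTX_cluster", ]
  props <- c(indel = 0.387, nagnag = 0.138, homologous_substitution = 0.213,
             cterm_substitution = 0.152, nterm_substitution = 0.085,
             internal_substitution = 0.007, two_proteins = 0.018)
  want <- splicepep:::apportion(nrow(own), props)
  names(want) <- names(props)
  got <- table(factor(own$kind, names(props)))
  expect_identical(as.integer(got), unname(want))
})

test_that("zero artifact rates leave the filters nothing to remove", {
  syn <- generate_gene_set(20L, seed = 23L)
  det <- simulate_detections(syn, seed = 24L,
                             artifact_rates = c(non_tryptic = 0,
                                                unsupported_missed = 0,
                                                single_experiment = 0,
                                                sub_score = 0))
  expect_true(all(det$truth$class == "clean"))
  for (ds in names(det$tables)) {
    out <- enforce_missed_cleavage_support(
      apply_dataset_filters(det$tables[[ds]], det$configs[[ds]]))
    expect_identical(sum(out$audit), 0L)
    expect_identical(nrow(out$peptides), nrow(det$tables[[ds]]))
  }
})

test_that("alternative-only peptides appear at roughly 1/51 the principal rate", {
  syn <- big_synth()
  det <- big_detect()
  gs <- det$gene_set
  db1 <- build_peptide_db(gs, max_missed = 1L)
  counts <- table(det$truth$dataset[det$truth$class == "clean"],
                  dnn = NULL)
  # classify each clean detection record as principal-only / alt-only
  prin <- gs$isoforms$isoform_id[gs$isoforms$principal]
  cl <- det$truth[det$truth$class == "clean", ]
  cl$canon <- canonical_il(cl$sequence)
  iso_of <- split(db1$isoform_id, db1$canon_seq)
  status <- vapply(cl$canon, function(cn) {
    isos <- unique(iso_of[[cn]])
    if (is.null(isos)) return("other")
    p <- any(isos %in% prin)
    a <- any(!isos %in% prin)
    if (p && !a) "principal_only" else if (a && !p) "alt_only" else "shared"
  }, character(1))
  n_p <- sum(status == "principal_only")
  n_a <- sum(status == "alt_only")
  # normalize by the size of each side's peptide universe: per-peptide
  # detection frequency of alternative-only peptides should be far below
  # the principal-only frequency (the 50:1 dominance), but not zero
  u <- vapply(iso_of, function(isos) {
    isos <- unique(isos)
    p <- any(isos %in% prin); a <- any(!isos %in% prin)
    if (p && !a) "principal_only" else if (a && !p) "alt_only" else "shared"
  }, character(1))
  rate_p <- n_p / sum(u == "principal_only")
  rate_a <- n_a / sum(u == "alt_only")
  expect_lt(rate_a / rate_p, 0.12)
  expect_gt(n_a, 0L)
})

test_that("species fixtures recover every planted origin node", {
  fx <- generate_species_fixtures(n_features = 50L, seed = 5L)
  rec <- vapply(seq_len(nrow(fx$origins)), function(i)
    dollo_origin(fx$tree, unlist(fx$presence[i, ]))$node ==
      fx$origins$node[i], logical(1))
  expect_identical(mean(rec), 1)
  # human-only features stay on the human branch
  solo <- which(fx$origins$label == "human")
  for (i in solo)
    expect_identical(sum(unlist(fx$presence[i, ])), 1L)
  # hits land within the assignment window of their source gene
  for (sp in c("zebrafish", "human")) {
    h <- fx$hits[fx$hits$species == sp, ]
    if (!nrow(h)) next
    res <- assign_hits_to_genes(h, fx$gene_tables[[sp]])
    expect_identical(res$assigned, h$target_gene)
  }
})
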