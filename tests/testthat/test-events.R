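# hand-constructed three-exon gene: e1 (10 codons), e2 (30), e3 (10);
# the alt isoform skips e2
skip_gene <- function() {
  aa1 <- "MAAAAAAAAK"; aa2 <- strrep("GGCDE", 6); aa3 <- "WWWWWWWWWR"
  iso <- data.frame(isoform_id = c("SK.1", "SK.2"), gene_id = "SK",
                    protein = c(paste0(aa1, aa2, aa3), paste0(aa1, aa3)),
                    stringsAsFactors = FALSE)
  exons <- rbind(
    data.frame(isoform_id = "SK.1", chrom = "chrT",
               start = c(0L, 100L, 300L), end = c(30L, 190L, 330L),
               strand = "+", rank = 1:3),
    data.frame(isoform_id = "SK.2", chrom = "chrT",
               start = c(0L, 300L), end = c(30L, 330L),
               strand = "+", rank = 1:2))
  gene_set(iso, exons)
}

test_that("codon projection matches shared exons and exposes the skip", {
  gs <- skip_gene()
  proj <- project_isoform_pair(gs, "SK.1", "SK.2")
  expect_identical(proj$method, "codon")
  expect_identical(nrow(proj$pairs), 20L)        # e1 + e3 codons
  evs <- extract_events(gs, "SK.1", "SK.2")
  expect_length(evs, 1L)
  expect_identical(evs[[1]]$main_segment, c(11L, 40L))
  expect_null(evs[[1]]$alt_segment)
  expect_identical(classify_event(evs[[1]])[1], "indel")
  # identical isoforms: full match, no events
  expect_length(extract_events(gs, "SK.1", "SK.1"), 0L)
  expect_error(project_isoform_pair(skip_gene(), "SK.1", "SK.1x"))
})

test_that("pure truncations of the main isoform emit no events", {
  iso <- data.frame(isoform_id = c("T.1", "T.2", "T.3"), gene_id = "T",
                    protein = c("MAYCDEFGHKLMNPQRSTVW",
                                substr("MAYCDEFGHKLMNPQRSTVW", 1, 12),
                                substr("MAYCDEFGHKLMNPQRSTVW", 6, 20)),
                    stringsAsFactors = FALSE)
  gs <- gene_set(iso)
  expect_length(extract_events(gs, "T.1", "T.2"), 0L)  # prefix
  expect_length(extract_events(gs, "T.1", "T.3"), 0L)  # suffix
})

test_that("shared exons read in different frames stay unmatched", {
  syn <- big_synth()
  tp <- syn$truth$events[syn$truth$events$kind == "two_proteins", ]
  expect_gt(nrow(tp), 0)
  for (i in seq_len(nrow(tp))) {
    proj <- project_isoform_pair(syn$gene_set, tp$main_isoform_id[i],
                                 tp$alt_isoform_id[i])
    expect_identical(nrow(proj$pairs), 0L)
    evs <- extract_events(syn$gene_set, tp$main_isoform_id[i],
                          tp$alt_isoform_id[i])
    expect_length(evs, 1L)
    expect_identical(classify_event(evs[[1]])[1], "two_proteins")
  }
})

test_that("indel/NAGNAG boundary sits between 4 and 5 residues", {
  mk_indel <- function(n) {
    structure(list(gene_id = "G", main_isoform_id = "a",
                   alt_isoform_id = "b",
                   main_segment = c(10L, 10L + n - 1L), alt_segment = NULL,
                   main_len = 100L, alt_len = 100L - n,
                   main_seq = strrep("A", n), alt_seq = "",
                   main_flank = c(9L, 10L + n), alt_flank = c(9L, 10L),
                   no_match = FALSE), class = "splice_event")
  }
  expect_identical(classify_event(mk_indel(1L))[1], "nagnag")
  expect_identical(classify_event(mk_indel(4L))[1], "nagnag")
  expect_identical(classify_event(mk_indel(5L))[1], "indel")
  expect_identical(classify_event(mk_indel(13L))[1], "indel")
})

test_that("substitution kinds depend on position and homology", {
  mk_sub <- function(ms, me, as, ae, main_len, alt_len, seq_m, seq_a) {
    structure(list(gene_id = "G", main_isoform_id = "a",
                   alt_isoform_id = "b",
                   main_segment = c(ms, me), alt_segment = c(as, ae),
                   main_len = main_len, alt_len = alt_len,
                   main_seq = seq_m, alt_seq = seq_a,
                   main_flank = c(ms - 1L, me + 1L),
                   alt_flank = c(as - 1L, ae + 1L),
                   no_match = FALSE), class = "splice_event")
  }
  set.seed(5)
  s1 <- random_protein(40, include_p = FALSE)
  s2 <- random_protein(8, include_p = FALSE)
  # internal non-homologous swap (KIF23-like: 100 residues for 6)
  ev <- mk_sub(20L, 119L, 20L, 25L, 200L, 106L, random_protein(100),
               random_protein(6))
  expect_identical(classify_event(ev, seed = 1L)[1], "internal_substitution")
  # N-terminal non-homologous substitution
  ev <- mk_sub(1L, 40L, 1L, 8L, 100L, 68L, s1, s2)
  expect_identical(classify_event(ev, seed = 1L)[1], "nterm_substitution")
  # C-terminal
  ev <- mk_sub(61L, 100L, 61L, 68L, 100L, 68L, s1, s2)
  expect_identical(classify_event(ev, seed = 1L)[1], "cterm_substitution")
  # homologous segments win over the terminal label
  ev <- mk_sub(1L, 40L, 1L, 40L, 100L, 100L, s1, s1)
  expect_identical(classify_event(ev, seed = 1L)[1],
                   "homologous_substitution")
  # swapping main/alt preserves the kind for substitutions
  swap <- function(e) {
    structure(list(gene_id = e$gene_id, main_isoform_id = e$alt_isoform_id,
                   alt_isoform_id = e$main_isoform_id,
                   main_segment = e$alt_segment, alt_segment = e$main_segment,
                   main_len = e$alt_len, alt_len = e$main_len,
                   main_seq = e$alt_seq, alt_seq = e$main_seq,
                   main_flank = e$alt_flank, alt_flank = e$main_flank,
                   no_match = e$no_match), class = "splice_event")
  }
  for (e in list(mk_sub(20L, 119L, 20L, 25L, 200L, 106L,
                        random_protein(100), random_protein(6)),
                 mk_sub(1L, 40L, 1L, 40L, 100L, 100L, s1, s1))) {
    expect_identical(classify_event(e, seed = 1L)[1],
                     classify_event(swap(e), seed = 1L)[1])
  }
})

test_that("classification is total over the synthetic event universe", {
  fit <- small_scan()
  kinds <- vapply(fit$events, `[[`, "", "kind")
  lev <- c("indel", "nagnag", "homologous_substitution",
           "cterm_substitution", "nterm_substitution",
           "internal_substitution", "two_proteins")
  expect_true(all(kinds %in% lev))
  expect_identical(sum(table(factor(kinds, lev))), length(fit$events))
})

test_that("segment homology test behaves at both extremes", {
  set.seed(9)
  seg <- random_protein(50, include_p = FALSE)
  h <- test_segment_homology(seg, seg, seed = 1L)
  expect_true(h$homologous)
  expect_equal(h$empirical_p, 1 / 201)
  # reversal of an unrelated random 50-mer: not homologous
  h2 <- test_segment_homology(seg, paste(rev(strsplit(random_protein(50),
                                                      "")[[1]]),
                                         collapse = ""), seed = 1L)
  expect_false(h2$homologous)
  # a diverged pair at ~33% identity over a domain-sized segment
  # (trypsin-domain-like case) is still called homologous
  base <- random_protein(120, include_p = FALSE)
  chars <- strsplit(base, "")[[1]]
  keep <- sort(sample(120, 40))
  div <- chars
  for (i in setdiff(seq_len(120), keep))
    div[i] <- sample(setdiff(c("A", "D", "E", "G", "N", "Q", "S", "T", "V"),
                             chars[i]), 1)
  h3 <- test_segment_homology(base, paste(div, collapse = ""), seed = 1L)
  expect_true(h3$homologous)
  # short segments are never called
  expect_false(test_segment_homology("A", "A")$homologous)
})

test_that("both-sides peptide evidence follows the junction rules", {
  gs <- skip_gene()
  main_prot <- gs_protein(gs, "SK.1")
  alt_prot <- gs_protein(gs, "SK.2")
  ev <- splicepep:::classify_events(extract_events(gs, "SK.1", "SK.2"))[[1]]
  # deletion side needs a junction-crossing peptide on the short isoform;
  # peptides inside the flanking shared regions do not count
  m_flank <- map_peptides(c("MAAAAAAAAK", "WWWWWWWWWR"), gs)
  expect_null(detect_ise(ev, m_flank))
  # segment-overlapping peptide on the long isoform + junction peptide on
  # the short isoform
  junction_pep <- substr(alt_prot, 7L, 14L)    # spans positions 10|11
  seg_pep <- substr(main_prot, 15L, 24L)       # inside the skipped exon
  m_ok <- map_peptides(c(junction_pep, seg_pep), gs)
  ise <- detect_ise(ev, m_ok)
  expect_s3_class(ise, "ise")
  expect_identical(ise$main_side_peptides, canonical_il(seg_pep))
  expect_identical(ise$alt_side_peptides, canonical_il(junction_pep))
  expect_gt(length(ise$main_side_peptides), 0L)
  expect_gt(length(ise$alt_side_peptides), 0L)
})

test_that("single-residue NAGNAG insertions are detectable (VDAC3-like)", {
  gs <- toy_insertion_gene()
  evs <- splicepep:::classify_events(extract_events(gs, "TOY.1", "TOY.2"))
  expect_length(evs, 1L)
  ev <- evs[[1]]
  expect_identical(ev$kind, "nagnag")
  # long-isoform peptide covers the insertion, short-isoform peptide spans
  # the junction
  m <- map_peptides(c("CCCCWWWGGGGK", "CCCCGGGGK"), gs)
  ise <- detect_ise(ev, m)
  expect_s3_class(ise, "ise")
  # with only one side covered there is no ISE
  expect_null(detect_ise(ev, map_peptides("CCCCWWWGGGGK", gs)))
})

test_that("duplicate events collapse on (gene, kind, genomic key)", {
  syn <- small_synth()
  gs <- merge_gene_clusters(syn$gene_set, syn$truth$clusters)
  gs <- mark_principal(gs)
  # the cluster gene: same first-exon swap seen from several member pairs
  evs <- list()
  main <- "CLUM01.1"
  for (alt in setdiff(gs_isoforms_of(gs, "UGTX_cluster"), main))
    evs <- c(evs, extract_events(gs, main, alt))
  evs <- splicepep:::classify_events(evs, seed = 1L)
  expect_identical(length(dedupe_events(c(evs, evs))), length(evs))
  # distinct skips in one gene stay distinct
  fit <- small_scan()
  keys <- vapply(fit$events, function(e)
    paste(e$gene_id, e$kind, e$genomic_key), character(1))
  expect_identical(anyDuplicated(keys), 0L)
  # brute-force key grouping matches
  raw <- c(fit$events, fit$events)
  expect_identical(length(dedupe_events(raw)), length(unique(keys)))
})
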