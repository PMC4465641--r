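test_that("GTF/FASTA round trip preserves proteins and drops flagged records", {
  syn <- generate_gene_set(15L, seed = 3L)
  d <- withr::local_tempdir()
  write_gene_set(syn$gene_set, file.path(d, "a.gtf"), file.path(d, "a.faa"),
                 genome = syn$genome, genome_path = file.path(d, "g.fa"))
  gs2 <- load_gene_set(file.path(d, "a.gtf"), file.path(d, "a.faa"),
                       genome_fasta_path = file.path(d, "g.fa"),
                       par_regions = synth_par_regions())
  expect_false(any(gs2$isoforms$read_through))
  expect_false(any(gs2$isoforms$isoform_id %in%
                     syn$truth$readthrough_isoforms))
  expect_false(any(gs2$isoforms$gene_id %in% syn$truth$par_genes))
  m <- match(gs2$isoforms$isoform_id, syn$gene_set$isoforms$isoform_id)
  expect_identical(gs2$isoforms$protein, syn$gene_set$isoforms$protein[m])
  # everything not a decoy survives
  keep <- !syn$gene_set$isoforms$gene_id %in% syn$truth$par_genes &
    !syn$gene_set$isoforms$read_through
  expect_setequal(gs2$isoforms$isoform_id,
                  syn$gene_set$isoforms$isoform_id[keep])
  # retained CDS chains are whole codons
  for (id in head(gs2$isoforms$isoform_id, 10)) {
    e <- gs2$exons[gs2$exons$isoform_id == id, ]
    expect_identical(sum(e$end - e$start) %% 3L, 0L)
  }
})

test_that("CDS translation matches the protein FASTA on a hand toy", {
  # two-exon CDS translating to MKAAAAAAR: ATGAAA | GCTGCAGCCGCGGCTGCACGT
  d <- withr::local_tempdir()
  writeLines(c(">chrZ", paste0(strrep("T", 10), "ATGAAA", strrep("T", 5),
                               "GCTGCAGCCGCGGCTGCACGT", strrep("T", 10))),
             file.path(d, "g.fa"))
  writeLines(c(
    paste0("chrZ\ttoy\tCDS\t11\t16\t.\t+\t0\t",
           'gene_id "G1"; transcript_id "T1";'),
    paste0("chrZ\ttoy\tCDS\t22\t42\t.\t+\t0\t",
           'gene_id "G1"; transcript_id "T1";')),
    file.path(d, "a.gtf"))
  gs <- load_gene_set(file.path(d, "a.gtf"), NULL,
                      genome_fasta_path = file.path(d, "g.fa"))
  expect_identical(gs$isoforms$protein, "MKAAAAAAR")
})

test_that("single-isoform gene with no flags loads unchanged", {
  syn <- generate_gene_set(4L, seed = 5L, frac_single = 1,
                           include_cluster = FALSE, n_readthrough = 0L,
                           n_par_decoys = 0L)
  d <- withr::local_tempdir()
  write_gene_set(syn$gene_set, file.path(d, "a.gtf"), file.path(d, "a.faa"))
  gs2 <- load_gene_set(file.path(d, "a.gtf"), file.path(d, "a.faa"))
  expect_setequal(gs2$isoforms$isoform_id, syn$gene_set$isoforms$isoform_id)
  m <- match(syn$gene_set$isoforms$isoform_id, gs2$isoforms$isoform_id)
  expect_identical(gs2$isoforms$protein[m], syn$gene_set$isoforms$protein)
})

test_that("malformed GTF lines are rejected with a line number", {
  d <- withr::local_tempdir()
  writeLines(c("# comment",
               paste0("chr1\tx\tCDS\t1\t9\t.\t+\t0\t",
                      'gene_id "G"; transcript_id "T";'),
               "chr1\tbroken line"), file.path(d, "bad.gtf"))
  expect_error(load_gene_set(file.path(d, "bad.gtf"), NULL),
               "line 3")
})

test_that("cluster merging pools isoforms, keeps provenance, is idempotent", {
  syn <- generate_gene_set(20L, seed = 9L)
  gs <- syn$gene_set
  cl <- syn$truth$clusters
  members <- strsplit(cl$member_gene_ids, ";")[[1]]
  n_before <- nrow(gs$genes)
  merged <- merge_gene_clusters(gs, cl)
  expect_identical(nrow(merged$genes), n_before - length(members) + 1L)
  expect_setequal(gs_isoforms_of(merged, cl$cluster_name),
                  gs$isoforms$isoform_id[gs$isoforms$gene_id %in% members])
  src <- strsplit(merged$genes$source_genes[
    merged$genes$gene_id == cl$cluster_name], ";")[[1]]
  expect_setequal(src, members)
  # idempotent
  expect_identical(merge_gene_clusters(merged, cl), merged)
  # unknown member errors with the id
  bad <- data.frame(cluster_name = "X", member_gene_ids = "NOPE1;NOPE2")
  expect_error(merge_gene_clusters(gs, bad), "NOPE1")
})

test_that("two disjoint 2-gene clusters reduce the gene count by two", {
  syn <- generate_gene_set(10L, seed = 13L, include_cluster = FALSE,
                           n_par_decoys = 0L, n_readthrough = 0L)
  gs <- syn$gene_set
  g <- gs$genes$gene_id
  cl <- data.frame(cluster_name = c("CA", "CB"),
                   member_gene_ids = c(paste(g[1:2], collapse = ";"),
                                       paste(g[3:4], collapse = ";")))
  merged <- merge_gene_clusters(gs, cl)
  expect_identical(nrow(merged$genes), nrow(gs$genes) - 2L)
  expect_identical(merge_gene_clusters(gs, cl[0, ]), gs)  # empty list no-op
})

test_that("principal selection honours the table, falls back to longest", {
  iso <- data.frame(isoform_id = c("B", "A", "C"), gene_id = "G",
                    protein = c(strrep("A", 90), strrep("A", 100),
                                strrep("A", 100)),
                    stringsAsFactors = FALSE)
  gs <- gene_set(iso)
  expect_identical(select_principal(gs, "G"), "A")   # longest, lexicographic
  tab <- data.frame(gene_id = "G", isoform_id = "B")
  expect_identical(select_principal(gs, "G", tab), "B")
  expect_error(select_principal(gs, "G",
                                data.frame(gene_id = "G", isoform_id = "Z")),
               "unknown isoform")
  # deterministic
  expect_identical(select_principal(gs, "G"), select_principal(gs, "G"))
  # single isoform gene
  gs1 <- gene_set(iso[1, ])
  expect_identical(select_principal(gs1, "G"), "B")
  expect_error(select_principal(gs, "NOGENE"))
})
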