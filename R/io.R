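# Writers for the standard interchange formats, so synthetic fixtures can
# feed the loaders unchanged.

#' Write a gene_set as GTF + protein FASTA (+ genome FASTA)
#'
#' Emits one CDS feature per exon (Ensembl GTF dialect, 1-based inclusive
#' coordinates) with `gene_id`/`transcript_id` attributes and a
#' `tag "readthrough_transcript"` attribute on flagged isoforms. Output is
#' deterministic: fixed ordering, no timestamps.
#'
#' @param gs a [gene_set()].
#' @param gtf_path,fasta_path output paths.
#' @param genome,genome_path optional named chromosome sequences and
#'   output path for a genome FASTA.
#' @return Invisibly, the GTF path.
#' @export
write_gene_set <- function(gs, gtf_path, fasta_path, genome = NULL,
                           genome_path = NULL) {
  iso <- gs$isoforms[order(gs$isoforms$isoform_id), , drop = FALSE]
  lines <- character()
  for (i in seq_len(nrow(iso))) {
    id <- iso$isoform_id[i]
    e <- gs_exons_of(gs, id)
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     iso$gene_id[i], id)
    if (iso$read_through[i])
      attrs <- paste0(attrs, ' tag "readthrough_transcript";')
    lines <- c(lines, sprintf("%s\tsynth\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                              e$chrom, e$start + 1L, e$end, e$strand, attrs))
  }
  writeLines(lines, gtf_path)
  writeLines(as.vector(rbind(paste0(">", iso$isoform_id), iso$protein)),
             fasta_path)
  if (!is.null(genome) && !is.null(genome_path))
    writeLines(as.vector(rbind(paste0(">", names(genome)),
                               unlist(genome))), genome_path)
  invisible(gtf_path)
}

#' Write per-dataset peptide tables to TSV
#' @param tables named list of peptide record data.frames.
#' @param dir output directory (created if needed).
#' @return character vector of file paths.
#' @export
write_peptide_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(tables), function(ds) {
    p <- file.path(dir, paste0(ds, ".tsv"))
    utils::write.table(tables[[ds]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p
  }, character(1))
  paths
}

#' Default rooted species tree for exon dating
#'
#' Six taxa spanning the vertebrates: lamprey as the jawless outgroup,
#' then ray-finned fishes (spotted gar; zebrafish and fugu as teleosts)
#' and lobe-finned lineages (coelacanth, human). Branch lengths are
#' approximate divergence times in million years; internal nodes are
#' labelled.
#'
#' @return an [ape::read.tree()] `phylo` object.
#' @export
default_species_tree <- function() {
  ape::read.tree(text = paste0(
    "(lamprey:530,((gar:315,(zebrafish:230,fugu:230)teleostei:85)",
    "actinopterygii:115,(coelacanth:415,human:415)sarcopterygii:15)",
    "gnathostomata:100)vertebrata;"))
}

#' Generate cross-species presence fixtures with known origins
#'
#' For each synthetic feature (e.g. a homologous exon), picks a planted
#' origin node on the species tree, marks the feature present in a subset
#' of descendant tips (always keeping tips in two different child
#' lineages, so the minimum-origin reconstruction is identifiable; random
#' losses elsewhere), and emits per-species similarity-hit tables whose
#' coordinates are consistent with window-based gene assignment.
#'
#' @param n_features number of features.
#' @param tree a rooted `phylo`; default [default_species_tree()].
#' @param seed RNG seed.
#' @param loss_prob probability that a non-anchor descendant tip lost the
#'   feature.
#' @return list with `presence` (feature x species logical data.frame),
#'   `origins` (planted truth: feature, node, label), `tree`, `hits` and
#'   `gene_tables` (per-species gene coordinate data.frames).
#' @export
generate_species_fixtures <- function(n_features = 50L,
                                      tree = default_species_tree(),
                                      seed = 1L, loss_prob = 0.3) {
  with_seed(seed, {
    ntip <- ape::Ntip(tree)
    nodes <- c(seq_len(ntip), (ntip + 1L):(ntip + tree$Nnode))
    labels <- c(tree$tip.label, tree$node.label %||%
                  paste0("node", (ntip + 1L):(ntip + tree$Nnode)))
    # restrict tip origins to human (features are discovered in human)
    cand <- c(match("human", tree$tip.label), (ntip + 1L):(ntip + tree$Nnode))
    origins <- sample(cand, n_features, replace = TRUE)
    pres <- matrix(FALSE, n_features, ntip,
                   dimnames = list(sprintf("feat%03d", seq_len(n_features)),
                                   tree$tip.label))
    for (f in seq_len(n_features)) {
      o <- origins[f]
      if (o <= ntip) { pres[f, o] <- TRUE; next }
      kids <- tree$edge[tree$edge[, 1] == o, 2]
      anchor <- vapply(kids[1:2], function(k)
        sample(rep(tips_under(tree, k), 2L), 1L), integer(1))
      desc <- tips_under(tree, o)
      keep <- union(anchor, desc[stats::runif(length(desc)) > loss_prob])
      pres[f, keep] <- TRUE
    }
    presence <- as.data.frame(pres)

    # per-species gene tables and hits near the "ortholog" gene
    gene_tables <- list(); hits <- list()
    for (sp in tree$tip.label) {
      n_genes <- 30L
      len <- round(stats::rlnorm(n_genes, log(20000), 0.6))
      start <- cumsum(c(1e5, utils::head(len, -1) + 2e5))
      gene_tables[[sp]] <- data.frame(
        gene_id = sprintf("%s_g%02d", sp, seq_len(n_genes)),
        chrom = "chr1", start = start, end = start + len,
        stringsAsFactors = FALSE)
      q95 <- as.numeric(stats::quantile(len, 0.95))
      for (f in which(pres[, sp])) {
        g <- (f %% n_genes) + 1L
        hs <- gene_tables[[sp]]$end[g] + round(stats::runif(1, 0, q95 / 4))
        hits[[length(hits) + 1L]] <- data.frame(
          hit_id = sprintf("%s_%s", rownames(pres)[f], sp), species = sp,
          chrom = "chr1", start = hs, end = hs + 120L,
          evalue = 10^stats::runif(1, -30, -3),
          query_exon_id = rownames(pres)[f],
          target_gene = gene_tables[[sp]]$gene_id[g],
          stringsAsFactors = FALSE)
      }
    }
    list(presence = presence,
         origins = data.frame(feature = rownames(pres), node = origins,
                              label = labels[origins],
                              stringsAsFactors = FALSE),
         tree = tree,
         hits = if (length(hits)) do.call(rbind, hits) else NULL,
         gene_tables = gene_tables)
  })
}

tips_under <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(node)
  out <- integer()
  stack <- node
  while (length(stack)) {
    n <- stack[1]; stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == n, 2]
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  sort(out)
}
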