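#' Load a transcript annotation into a gene_set
#'
#' Reads CDS features from a GTF/GFF3 file and per-isoform protein sequences
#' from a FASTA file (headers keyed by transcript id, first whitespace-
#' delimited token). Transcripts tagged as read-through and genes overlapping
#' configured pseudoautosomal regions can be dropped at load time, mirroring
#' the usual clean-up applied to reference annotations before peptide
#' mapping.
#'
#' When `genome_fasta_path` is supplied, each isoform's CDS is translated
#' (minus-strand exons reverse-complemented, exons concatenated in
#' transcription order) and used to fill in missing proteins and to check
#' provided ones; a mismatch raises a warning naming the transcript.
#'
#' @param gtf_path path to a GTF (Ensembl dialect) or GFF3 file.
#' @param protein_fasta_path path to a protein FASTA keyed by transcript id,
#'   or `NULL` when `genome_fasta_path` is given.
#' @param genome_fasta_path optional genome FASTA used to translate CDS.
#' @param drop_read_through drop transcripts carrying the read-through tag.
#' @param drop_pseudoautosomal drop genes overlapping `par_regions`.
#' @param par_regions pseudoautosomal regions: a data.frame with columns
#'   `chrom`, `start`, `end` (0-based half-open) or a BED file path.
#' @param readthrough_tag attribute tag marking read-through transcripts.
#' @return A [gene_set()].
#' @export
load_gene_set <- function(gtf_path, protein_fasta_path = NULL,
                          genome_fasta_path = NULL,
                          drop_read_through = TRUE,
                          drop_pseudoautosomal = TRUE,
                          par_regions = NULL,
                          readthrough_tag = "readthrough_transcript") {
  check_gtf_lines(gtf_path)
  gr <- rtracklayer::import(gtf_path)
  md <- S4Vectors::mcols(gr)
  keep <- !is.na(md$type) & md$type == "CDS"
  if (!any(keep)) stop("no CDS features in ", gtf_path, call. = FALSE)
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)

  tx <- as.character(md$transcript_id)
  gene <- as.character(md$gene_id)
  if (anyNA(tx) || anyNA(gene))
    stop("CDS features missing transcript_id/gene_id attributes",
         call. = FALSE)

  rt_tx <- character()
  if ("tag" %in% names(md)) {
    tags <- md$tag
    has_rt <- if (methods::is(tags, "CharacterList") || is.list(tags))
      vapply(tags, function(t) readthrough_tag %in% t, logical(1))
    else !is.na(tags) & tags == readthrough_tag
    rt_tx <- unique(tx[has_rt])
  }

  exons <- data.frame(
    isoform_id = tx,
    gene_id = gene,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  # transcription order: plus strand by ascending start, minus by descending
  ord <- order(exons$isoform_id,
               ifelse(exons$strand == "-", -exons$start, exons$start))
  exons <- exons[ord, , drop = FALSE]
  exons$rank <- stats::ave(seq_len(nrow(exons)), exons$isoform_id,
                           FUN = seq_along)

  iso <- unique(exons[, c("isoform_id", "gene_id")])
  iso$read_through <- iso$isoform_id %in% rt_tx
  iso$principal <- FALSE

  prots <- if (!is.null(protein_fasta_path)) read_protein_fasta(protein_fasta_path)
           else character()
  iso$protein <- unname(prots[iso$isoform_id])

  gs <- gene_set(isoforms = iso,
                 exons = exons[, c("isoform_id", "chrom", "start", "end",
                                   "strand", "rank")])

  if (!is.null(genome_fasta_path)) {
    genome <- read_genome_fasta(genome_fasta_path)
    for (i in seq_len(nrow(gs$isoforms))) {
      id <- gs$isoforms$isoform_id[i]
      tr <- translate_cds(cds_nt_seq(gs, id, genome))
      if (is.na(gs$isoforms$protein[i])) {
        gs$isoforms$protein[i] <- tr
      } else if (!identical(gs$isoforms$protein[i], tr)) {
        warning("protein sequence of ", id, " does not match its CDS translation",
                call. = FALSE)
      }
    }
  }

  missing <- is.na(gs$isoforms$protein)
  if (any(missing)) {
    warning("dropping ", sum(missing),
            " coding transcript(s) without a protein sequence: ",
            paste(utils::head(gs$isoforms$isoform_id[missing], 5), collapse = ", "),
            call. = FALSE)
    gs <- subset_isoforms(gs, gs$isoforms$isoform_id[!missing])
  }

  if (drop_read_through && any(gs$isoforms$read_through))
    gs <- subset_isoforms(gs, gs$isoforms$isoform_id[!gs$isoforms$read_through])

  if (drop_pseudoautosomal && !is.null(par_regions)) {
    par <- if (is.character(par_regions)) read_bed_regions(par_regions)
           else par_regions
    bad_genes <- unique(unlist(lapply(seq_len(nrow(par)), function(i) {
      hit <- gs$exons$chrom == par$chrom[i] &
        gs$exons$start < par$end[i] & gs$exons$end > par$start[i]
      vapply(unique(gs$exons$isoform_id[hit]), function(id) gs_gene_of(gs, id),
             character(1))
    })))
    if (length(bad_genes))
      gs <- subset_isoforms(
        gs, gs$isoforms$isoform_id[!gs$isoforms$gene_id %in% bad_genes])
  }
  gs
}

check_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 9L)) {
    bad <- which(body)[which(nf < 9L)[1]]
    stop("malformed GTF/GFF line ", bad, " in ", path,
         " (fewer than 9 tab-separated fields)", call. = FALSE)
  }
  invisible(TRUE)
}

read_protein_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  out <- as.character(ss)
  names(out) <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  out
}

read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.list(as.character(ss))
  names(out) <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  out
}

read_bed_regions <- function(path) {
  b <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  data.frame(chrom = b[[1]], start = as.integer(b[[2]]),
             end = as.integer(b[[3]]), stringsAsFactors = FALSE)
}

subset_isoforms <- function(gs, keep_ids) {
  iso <- gs$isoforms[gs$isoforms$isoform_id %in% keep_ids, , drop = FALSE]
  ex <- gs$exons[gs$exons$isoform_id %in% keep_ids, , drop = FALSE]
  genes <- gs$genes[gs$genes$gene_id %in% iso$gene_id, , drop = FALSE]
  gene_set(iso, ex, genes)
}

#' Merge annotated gene clusters into single genes
#'
#' Some loci are annotated as clusters of near-identical "genes" that share a
#' common set of 3' (or 5') exons joined to variable homologous exons; for
#' splice-event analysis these are best treated as splice variants of one
#' gene. Each cluster's member genes are replaced by a single gene (named
#' after the cluster) whose isoform set is the union of the members'
#' isoforms; original gene ids are retained as provenance.
#'
#' Re-applying the same cluster definitions is a no-op.
#'
#' @param gs a [gene_set()].
#' @param clusters a list of `list(cluster_name =, member_gene_ids =)`, a
#'   data.frame with columns `cluster_name` and `member_gene_ids`
#'   (`;`-joined), or a YAML file path with entries of the same shape.
#' @return The merged [gene_set()].
#' @export
merge_gene_clusters <- function(gs, clusters) {
  clusters <- normalize_clusters(clusters)
  for (cl in clusters) {
    name <- cl$cluster_name
    members <- cl$member_gene_ids
    if (length(members) < 2L)
      stop("cluster ", name, " needs >=2 member genes", call. = FALSE)
    present <- members %in% gs$genes$gene_id
    if (!all(present)) {
      # idempotence: member already merged into this cluster gene?
      src <- if (name %in% gs$genes$gene_id)
        strsplit(gs$genes$source_genes[gs$genes$gene_id == name], ";")[[1]]
      else character()
      merged <- members[!present] %in% src
      if (!all(merged))
        stop("unknown gene id(s) in cluster ", name, ": ",
             paste(members[!present][!merged], collapse = ", "), call. = FALSE)
      members <- members[present]
      if (!length(members)) next
      members <- c(members, name)
    }
    sel <- gs$isoforms$gene_id %in% members
    gs$isoforms$gene_id[sel] <- name
    old_src <- unlist(strsplit(
      gs$genes$source_genes[gs$genes$gene_id %in% c(members, name)], ";"))
    gs$genes <- gs$genes[!gs$genes$gene_id %in% c(members, name), , drop = FALSE]
    gs$genes <- rbind(gs$genes,
                      data.frame(gene_id = name,
                                 source_genes = paste(sort(unique(old_src)),
                                                      collapse = ";"),
                                 stringsAsFactors = FALSE))
    rownames(gs$genes) <- NULL
  }
  gs
}

normalize_clusters <- function(clusters) {
  if (is.character(clusters) && length(clusters) == 1L) {
    y <- yaml_read(clusters)
    return(lapply(y, function(cl)
      list(cluster_name = cl$cluster_name,
           member_gene_ids = unlist(cl$member_gene_ids))))
  }
  if (is.data.frame(clusters)) {
    return(lapply(seq_len(nrow(clusters)), function(i)
      list(cluster_name = clusters$cluster_name[i],
           member_gene_ids = strsplit(clusters$member_gene_ids[i], ";")[[1]])))
  }
  clusters
}

yaml_read <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading cluster YAML requires the yaml package", call. = FALSE)
  yaml::read_yaml(path)
}

#' Select the principal isoform of a gene
#'
#' Uses an externally supplied principal-isoform table when available
#' (APPRIS-style: the curated reference isoform per gene); otherwise falls
#' back to the longest protein, ties broken by lexicographically smallest
#' isoform id. The fallback is a documented approximation of curated
#' principal-isoform calls.
#'
#' @param gs a [gene_set()].
#' @param gene_id gene to resolve.
#' @param principal_table optional data.frame with columns `gene_id`,
#'   `isoform_id`.
#' @return The principal `isoform_id`.
#' @export
select_principal <- function(gs, gene_id, principal_table = NULL) {
  ids <- gs_isoforms_of(gs, gene_id)
  if (!length(ids)) stop("gene has no isoforms: ", gene_id, call. = FALSE)
  if (!is.null(principal_table)) {
    hit <- principal_table$isoform_id[principal_table$gene_id == gene_id]
    if (length(hit)) {
      hit <- hit[1]
      if (!hit %in% ids)
        stop("principal table names unknown isoform ", hit, " for gene ",
             gene_id, call. = FALSE)
      return(hit)
    }
  }
  len <- nchar(vapply(ids, function(i) gs_protein(gs, i), character(1)))
  ids[order(-len, ids)][1]
}

#' Mark principal isoforms across a gene_set
#'
#' Applies [select_principal()] to every gene and sets the `principal` flag.
#'
#' @inheritParams select_principal
#' @return The [gene_set()] with `principal` flags set (one per gene).
#' @export
mark_principal <- function(gs, principal_table = NULL) {
  pr <- vapply(gs_gene_ids(gs), function(g)
    select_principal(gs, g, principal_table), character(1))
  gs$isoforms$principal <- gs$isoforms$isoform_id %in% pr
  gs
}
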