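#' Gene-set container
#'
#' A `gene_set` holds a normalized view of a transcript annotation: one row
#' per protein isoform plus the ordered CDS exon chain of each isoform.
#' Genomic coordinates are stored 0-based half-open internally (GTF input is
#' converted on load); protein coordinates are 1-based throughout.
#'
#' @param isoforms data.frame with columns `isoform_id`, `gene_id`,
#'   `protein` (amino-acid string), and optionally logical `read_through`
#'   and `principal`.
#' @param exons data.frame with columns `isoform_id`, `chrom`, `start`,
#'   `end` (0-based half-open CDS portion), `strand` (`"+"`/`"-"`) and
#'   `rank` (1 = first exon in transcription direction). May be empty when
#'   only protein sequences are available.
#' @param genes optional data.frame with columns `gene_id` and
#'   `source_genes` (`;`-joined provenance after cluster merging).
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(isoforms, exons = NULL, genes = NULL) {
  stopifnot(is.data.frame(isoforms),
            all(c("isoform_id", "gene_id", "protein") %in% names(isoforms)))
  if (anyDuplicated(isoforms$isoform_id))
    stop("duplicated isoform_id in gene_set", call. = FALSE)
  if (is.null(isoforms$read_through)) isoforms$read_through <- FALSE
  if (is.null(isoforms$principal))  isoforms$principal <- FALSE
  if (is.null(exons))
    exons <- data.frame(isoform_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character(), rank = integer(),
                        stringsAsFactors = FALSE)
  stopifnot(all(c("isoform_id", "chrom", "start", "end", "strand", "rank")
                %in% names(exons)))
  if (nrow(exons) && any(exons$end < exons$start))
    stop("exon end < start", call. = FALSE)
  if (is.null(genes))
    genes <- data.frame(gene_id = unique(isoforms$gene_id),
                        source_genes = unique(isoforms$gene_id),
                        stringsAsFactors = FALSE)
  rownames(isoforms) <- NULL
  rownames(exons) <- NULL
  structure(list(isoforms = isoforms, exons = exons, genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set: %d genes, %d protein isoforms, %d CDS exon records\n",
              nrow(x$genes), nrow(x$isoforms), nrow(x$exons)))
  invisible(x)
}

gs_gene_ids <- function(gs) gs$genes$gene_id

#' Isoform ids of a gene
#' @param gs a [gene_set()].
#' @param gene_id gene id.
#' @return character vector of isoform ids.
#' @export
gs_isoforms_of <- function(gs, gene_id) {
  gs$isoforms$isoform_id[gs$isoforms$gene_id == gene_id]
}

#' Protein sequence of an isoform
#' @param gs a [gene_set()].
#' @param isoform_id isoform id.
#' @return the amino-acid sequence.
#' @export
gs_protein <- function(gs, isoform_id) {
  i <- match(isoform_id, gs$isoforms$isoform_id)
  if (is.na(i)) stop("unknown isoform: ", isoform_id, call. = FALSE)
  gs$isoforms$protein[i]
}

gs_gene_of <- function(gs, isoform_id) {
  i <- match(isoform_id, gs$isoforms$isoform_id)
  if (is.na(i)) stop("unknown isoform: ", isoform_id, call. = FALSE)
  gs$isoforms$gene_id[i]
}

gs_exons_of <- function(gs, isoform_id) {
  e <- gs$exons[gs$exons$isoform_id == isoform_id, , drop = FALSE]
  e[order(e$rank), , drop = FALSE]
}

# Genomic coordinates (0-based) of the CDS nucleotides of an isoform, in
# transcription order. NULL when the isoform has no exon records.
cds_nt_coords <- function(gs, isoform_id) {
  e <- gs_exons_of(gs, isoform_id)
  if (!nrow(e)) return(NULL)
  minus <- e$strand[1] == "-"
  coords <- unlist(lapply(seq_len(nrow(e)), function(i) {
    p <- seq.int(e$start[i], e$end[i] - 1L)
    if (minus) rev(p) else p
  }), use.names = FALSE)
  list(chrom = e$chrom[1], strand = e$strand[1], pos = coords)
}

# One key per codon: identical keys across isoforms mean the same genomic
# codon read in the same frame. Used for projecting isoform pairs.
codon_keys <- function(gs, isoform_id) {
  cc <- cds_nt_coords(gs, isoform_id)
  if (is.null(cc)) return(NULL)
  n <- length(cc$pos) %/% 3L
  if (n == 0L) return(character())
  m <- matrix(cc$pos[seq_len(3L * n)], nrow = 3L)
  paste0(cc$chrom, cc$strand, ":", m[1L, ], ".", m[2L, ], ".", m[3L, ])
}

# Translate a CDS nucleotide string (already in transcription direction,
# i.e. minus-strand exons reverse-complemented) to protein. Trailing stop
# codon, if present, is removed.
translate_cds <- function(nt) {
  n <- nchar(nt) - nchar(nt) %% 3L
  if (n < 3L) return("")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1L, n)),
    if.fuzzy.codon = "solve"))
  sub("\\*$", "", aa)
}

# CDS nucleotide string of an isoform given a genome (named character of
# chromosome sequences), in transcription direction.
cds_nt_seq <- function(gs, isoform_id, genome) {
  e <- gs_exons_of(gs, isoform_id)
  if (!nrow(e)) return(NULL)
  chrom_seq <- genome[[e$chrom[1]]]
  if (is.null(chrom_seq)) stop("chromosome missing from genome: ", e$chrom[1],
                               call. = FALSE)
  minus <- e$strand[1] == "-"
  parts <- vapply(seq_len(nrow(e)), function(i) {
    p <- substr(chrom_seq, e$start[i] + 1L, e$end[i])
    if (minus)
      p <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(p)))
    p
  }, character(1))
  paste(parts, collapse = "")
}
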