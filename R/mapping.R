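#' Map peptides onto isoform proteins
#'
#' Matches canonical (I/L-collapsed) peptide sequences against canonical
#' isoform proteins by exact substring search. Peptides matching isoforms
#' of two or more genes are discarded (with an audit count): only
#' gene-discriminating peptides carry usable isoform information. A peptide
#' is isoform-discriminating when it maps to a proper, non-empty subset of
#' its gene's isoforms.
#'
#' @param peptides character vector of peptide sequences, or a data.frame
#'   with a `canon_seq` (or `sequence`) column.
#' @param gs a [gene_set()].
#' @return A `peptide_matches` data.frame, one row per (peptide, isoform)
#'   occurrence: `canon_seq`, `gene_id`, `isoform_id`, `positions`
#'   (`;`-joined 1-based starts), `isoform_discriminating`. Attribute
#'   `audit` counts peptides dropped as multi-gene or unmapped.
#' @export
map_peptides <- function(peptides, gs) {
  seqs <- if (is.data.frame(peptides)) {
    if (!is.null(peptides$canon_seq)) peptides$canon_seq else peptides$sequence
  } else peptides
  seqs <- unique(canonical_il(seqs))
  prot <- canonical_il(gs$isoforms$protein)
  iso_ids <- gs$isoforms$isoform_id
  gene_ids <- gs$isoforms$gene_id
  n_iso_per_gene <- table(gene_ids)

  audit <- c(multi_gene = 0L, unmapped = 0L)
  rows <- vector("list", length(seqs))
  for (k in seq_along(seqs)) {
    pep <- seqs[k]
    hit <- which(grepl(pep, prot, fixed = TRUE))
    if (!length(hit)) { audit["unmapped"] <- audit["unmapped"] + 1L; next }
    genes <- unique(gene_ids[hit])
    if (length(genes) > 1L) { audit["multi_gene"] <- audit["multi_gene"] + 1L; next }
    pos <- vapply(hit, function(i) {
      p <- gregexpr(pep, prot[i], fixed = TRUE)[[1]]
      paste(p, collapse = ";")
    }, character(1))
    disc <- length(hit) < n_iso_per_gene[[genes]]
    rows[[k]] <- data.frame(canon_seq = pep, gene_id = genes,
                            isoform_id = iso_ids[hit], positions = pos,
                            isoform_discriminating = disc,
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(canon_seq = character(), gene_id = character(),
                         isoform_id = character(), positions = character(),
                         isoform_discriminating = logical(),
                         stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "audit") <- audit
  class(out) <- c("peptide_matches", "data.frame")
  out
}

match_positions <- function(matches, isoform_id, canon_seq) {
  r <- matches$positions[matches$isoform_id == isoform_id &
                           matches$canon_seq == canon_seq]
  if (!length(r)) return(integer())
  as.integer(strsplit(r[1], ";", fixed = TRUE)[[1]])
}

#' Pick the main isoform of a gene from peptide evidence
#'
#' The main isoform is the one supported by the most isoform-discriminating
#' peptides; ties are broken by the principal flag, then the longest
#' protein, then the lexicographically smallest isoform id. With no
#' discriminating peptides at all the principal isoform is returned.
#'
#' @param gs a [gene_set()] (principal flags set, see [mark_principal()]).
#' @param gene_id gene to resolve.
#' @param matches a `peptide_matches` object from [map_peptides()].
#' @return The main `isoform_id`.
#' @export
pick_main_isoform <- function(gs, gene_id, matches) {
  ids <- gs_isoforms_of(gs, gene_id)
  m <- matches[matches$gene_id == gene_id & matches$isoform_discriminating, ,
               drop = FALSE]
  counts <- vapply(ids, function(i)
    length(unique(m$canon_seq[m$isoform_id == i])), integer(1))
  if (all(counts == 0L)) {
    pr <- ids[gs$isoforms$principal[match(ids, gs$isoforms$isoform_id)]]
    if (length(pr)) return(pr[1])
    return(select_principal(gs, gene_id))
  }
  pr <- gs$isoforms$principal[match(ids, gs$isoforms$isoform_id)]
  len <- nchar(vapply(ids, function(i) gs_protein(gs, i), character(1)))
  ids[order(-counts, -pr, -len, ids)][1]
}

#' Count peptide evidence per gene
#'
#' Counts unique canonical peptides per gene among gene-discriminating
#' matches and flags genes reaching the detection threshold.
#'
#' @param matches a `peptide_matches` object.
#' @param threshold minimum unique peptides for a gene to count as
#'   detected (default 2).
#' @return data.frame with columns `gene_id`, `n_peptides`, `detected`.
#' @export
count_gene_evidence <- function(matches, threshold = 2L) {
  u <- unique(as.data.frame(matches)[, c("canon_seq", "gene_id")])
  tab <- table(u$gene_id)
  data.frame(gene_id = names(tab), n_peptides = as.integer(tab),
             detected = as.integer(tab) >= threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}
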