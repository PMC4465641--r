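#' Collapse isoleucine to leucine
#'
#' Search engines cannot distinguish leucine from isoleucine (identical
#' mass), so all sequence comparisons in this package are done on I/L-
#' collapsed ("canonical") strings: every `I` becomes `L`, other residues
#' are unchanged. The result is still a valid amino-acid string.
#'
#' @param seq character vector of amino-acid sequences (20-letter alphabet
#'   plus `X`).
#' @return Canonicalized character vector.
#' @export
canonical_il <- function(seq) {
  bad <- grepl(sprintf("[^%sX]", paste(AA20, collapse = "")), seq)
  if (any(bad))
    stop("non-amino-acid character in sequence: ",
         seq[bad][1], call. = FALSE)
  chartr("I", "L", seq)
}

enzyme_residues <- function(enzyme) {
  switch(enzyme,
         trypsin = c("K", "R"),
         lysc = "K",
         chymotrypsin = c("F", "W", "Y"),
         gluc = c("E", "D"),
         stop("unknown enzyme: ", enzyme, call. = FALSE))
}

# 1-based residue positions after which the enzyme cleaves.
cleavage_sites <- function(protein, enzyme, proline_rule = TRUE) {
  res <- strsplit(protein, "", fixed = TRUE)[[1]]
  n <- length(res)
  if (n < 2L) return(integer())
  sites <- which(res[-n] %in% enzyme_residues(enzyme))
  if (proline_rule) sites <- sites[res[sites + 1L] != "P"]
  sites
}

#' In-silico proteolytic digestion
#'
#' Cleaves a protein after the residues specific to the chosen enzyme
#' (trypsin: K/R, LysC: K, chymotrypsin: F/W/Y, GluC: E/D), optionally
#' suppressing cleavage before proline, and emits every product carrying
#' `0..max_missed` missed cleavages within the requested length window.
#'
#' @param protein amino-acid string.
#' @param enzyme one of `"trypsin"`, `"lysc"`, `"chymotrypsin"`, `"gluc"`.
#' @param max_missed maximum number of internal missed cleavage sites.
#' @param min_len,max_len peptide length window (residues).
#' @param proline_rule suppress cleavage when the following residue is `P`.
#' @return data.frame with columns `peptide`, `start` (1-based position in
#'   the protein) and `n_missed`.
#' @export
digest_protein <- function(protein, enzyme = "trypsin", max_missed = 0L,
                           min_len = 7L, max_len = Inf,
                           proline_rule = TRUE) {
  stopifnot(nchar(protein) > 0L, min_len >= 1L, max_missed >= 0L)
  sites <- cleavage_sites(protein, enzyme, proline_rule)
  bounds <- c(0L, sites, nchar(protein))
  nb <- length(bounds)
  out <- vector("list", nb - 1L)
  for (i in seq_len(nb - 1L)) {
    jmax <- min(nb, i + 1L + max_missed)
    js <- seq.int(i + 1L, jmax)
    s <- bounds[i] + 1L
    e <- bounds[js]
    len <- e - s + 1L
    ok <- len >= min_len & len <= max_len
    if (any(ok))
      out[[i]] <- data.frame(peptide = substring(protein, s, e[ok]),
                             start = s, n_missed = js[ok] - i - 1L,
                             stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(peptide = character(), start = integer(),
                      n_missed = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Number of internal (uncleaved) enzyme sites inside a peptide sequence.
count_internal_sites <- function(peptide, enzyme, proline_rule = TRUE) {
  vapply(peptide, function(p) length(cleavage_sites(p, enzyme, proline_rule)),
         integer(1), USE.NAMES = FALSE)
}

#' Build a unique-peptide database by in-silico digestion
#'
#' Digests every isoform protein in a gene set, canonicalizes the products
#' (I/L-collapsed) and indexes each distinct peptide by every
#' (gene, isoform, start) location where it occurs. Each peptide sequence
#' appears once in the database, however many isoforms share it; this is
#' the peptide universe used by the null abundance models.
#'
#' @param gs a [gene_set()].
#' @param enzyme,max_missed,min_len,max_len,proline_rule digestion
#'   parameters, see [digest_protein()]. The default (fully tryptic, >= 7
#'   residues, no missed cleavages) matches the null-model setup.
#' @return A `peptide_db`: data.frame with columns `canon_seq`, `gene_id`,
#'   `isoform_id`, `start`.
#' @export
build_peptide_db <- function(gs, enzyme = "trypsin", max_missed = 0L,
                             min_len = 7L, max_len = Inf,
                             proline_rule = TRUE) {
  iso <- gs$isoforms
  parts <- lapply(seq_len(nrow(iso)), function(i) {
    d <- digest_protein(iso$protein[i], enzyme, max_missed, min_len, max_len,
                        proline_rule)
    if (!nrow(d)) return(NULL)
    data.frame(canon_seq = canonical_il(d$peptide),
               gene_id = iso$gene_id[i], isoform_id = iso$isoform_id[i],
               start = d$start, stringsAsFactors = FALSE)
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  db <- if (length(parts)) unique(do.call(rbind, parts))
        else data.frame(canon_seq = character(), gene_id = character(),
                        isoform_id = character(), start = integer(),
                        stringsAsFactors = FALSE)
  rownames(db) <- NULL
  class(db) <- c("peptide_db", "data.frame")
  db
}

#' @export
print.peptide_db <- function(x, ...) {
  cat(sprintf("peptide_db: %d unique peptides, %d (gene, isoform, position) locations\n",
              length(unique(x$canon_seq)), nrow(x)))
  invisible(x)
}

#' Read a per-experiment peptide table
#'
#' Expected TSV columns: `sequence`, `dataset`, `engines` (`;`-joined),
#' `score`, `enzyme`, and optionally `n_missed`, `prev_aa`, `next_aa`
#' (flanking residues; `-` marks a protein terminus). `n_missed` is
#' recomputed from the sequence when absent; missing flanking-residue
#' columns default to `-` with a warning, since enzyme-specificity filtering
#' is then blind to the peptide's termini context.
#'
#' @param path TSV file path.
#' @param proline_rule used when recomputing `n_missed`.
#' @return data.frame of peptide records.
#' @export
read_peptide_table <- function(path, proline_rule = TRUE) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  need <- c("sequence", "dataset", "engines", "score", "enzyme")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("peptide table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(df$n_missed))
    df$n_missed <- mapply(function(p, e) count_internal_sites(p, e, proline_rule),
                          df$sequence, df$enzyme, USE.NAMES = FALSE)
  if (is.null(df$prev_aa) || is.null(df$next_aa)) {
    warning("peptide table ", path, " lacks prev_aa/next_aa context; ",
            "termini assumed conforming", call. = FALSE)
    if (is.null(df$prev_aa)) df$prev_aa <- "-"
    if (is.null(df$next_aa)) df$next_aa <- "-"
  }
  df
}

#' Write a peptide database to TSV
#' @param db a `peptide_db`.
#' @param path output file.
#' @export
write_peptide_db <- function(db, path) {
  utils::write.table(as.data.frame(db), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
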