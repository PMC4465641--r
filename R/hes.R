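#' Find mutually exclusive exon pairs in a gene
#'
#' Candidate pairs for homologous exon substitution (HES): CDS exons that
#' never co-occur in any annotated transcript of the gene, with both CDS
#' portions longer than 30 bp. By default one exon of the pair must belong
#' to the reference transcript (the one with the longest protein), the
#' other to a different transcript.
#'
#' @param gs a [gene_set()].
#' @param gene_id gene to scan (needs >= 2 isoforms).
#' @param reference_rule `"longest"` (pairs anchored on the longest-protein
#'   reference transcript) or `"all"` (all exon pairs).
#' @param min_cds_bp exclusive lower bound on CDS exon length (bp).
#' @return data.frame of candidate pairs with the exons' genomic
#'   coordinates and host isoforms.
#' @export
find_mutually_exclusive_pairs <- function(gs, gene_id,
                                          reference_rule = c("longest", "all"),
                                          min_cds_bp = 30L) {
  reference_rule <- match.arg(reference_rule)
  ids <- gs_isoforms_of(gs, gene_id)
  empty <- data.frame(gene_id = character(), exon_a = character(),
                      exon_b = character(), host_a = character(),
                      host_b = character(), stringsAsFactors = FALSE)
  if (length(ids) < 2L) return(empty)
  ex <- gs$exons[gs$exons$isoform_id %in% ids, , drop = FALSE]
  ex$key <- paste0(ex$chrom, ":", ex$start, "-", ex$end, ":", ex$strand)
  ex$len <- ex$end - ex$start
  keysets <- lapply(ids, function(i) unique(ex$key[ex$isoform_id == i]))
  names(keysets) <- ids
  len <- nchar(vapply(ids, function(i) gs_protein(gs, i), character(1)))
  ref <- ids[order(-len, ids)][1]

  uex <- unique(ex[, c("key", "len")])
  long_keys <- uex$key[uex$len > min_cds_bp]
  a_keys <- if (reference_rule == "longest")
    intersect(keysets[[ref]], long_keys) else long_keys
  host_of <- function(key) ids[vapply(ids, function(i) key %in% keysets[[i]],
                                      logical(1))]
  key_range <- function(key) as.integer(strsplit(key, "[:-]")[[1]][2:3])
  rows <- list()
  for (ka in a_keys) {
    for (kb in setdiff(long_keys, ka)) {
      if (reference_rule == "longest" && kb %in% keysets[[ref]]) next
      co_occur <- any(vapply(ids, function(i)
        ka %in% keysets[[i]] && kb %in% keysets[[i]], logical(1)))
      if (co_occur) next
      # genomically overlapping "pairs" are length variants of one exon
      # (e.g. tandem splice sites), not mutually exclusive exons
      ra <- key_range(ka); rb <- key_range(kb)
      if (ra[1] < rb[2] && rb[1] < ra[2]) next
      pair_key <- paste(sort(c(ka, kb)), collapse = "|")
      rows[[pair_key]] <- data.frame(
        gene_id = gene_id, exon_a = ka, exon_b = kb,
        host_a = host_of(ka)[1], host_b = host_of(kb)[1],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Protein segment encoded by a genomic exon within a host isoform,
# together with its 1-based protein interval.
exon_protein_segment <- function(gs, isoform_id, exon_key) {
  parts <- strsplit(exon_key, "[:-]")[[1]]
  chrom <- parts[1]; s <- as.integer(parts[2]); e <- as.integer(parts[3])
  cc <- cds_nt_coords(gs, isoform_id)
  if (is.null(cc) || cc$chrom != chrom) return(NULL)
  idx <- which(cc$pos >= s & cc$pos < e)
  if (!length(idx)) return(NULL)
  aa <- sort(unique((idx + 2L) %/% 3L))
  aa <- aa[aa >= 1L & aa <= nchar(gs_protein(gs, isoform_id))]
  if (!length(aa)) return(NULL)
  list(start = min(aa), end = max(aa),
       seq = substr(gs_protein(gs, isoform_id), min(aa), max(aa)))
}

#' Validate a mutually exclusive exon pair as homologous
#'
#' A candidate pair is accepted as a homologous exon substitution when (i)
#' the translated exon segments pass the permutation homology test, (ii)
#' the exons occupy equivalent relative positions in their host proteins
#' (midpoint fractions within `position_tolerance`), and (iii) neither
#' exon lies outside the gene's genomic locus (a guard against exons
#' captured from a paralogous neighbour gene or pseudogene).
#'
#' @param gs a [gene_set()].
#' @param candidate one row of [find_mutually_exclusive_pairs()] output.
#' @param homology_test function used for the sequence test; defaults to
#'   [test_segment_homology()].
#' @param position_tolerance maximum difference between the exons'
#'   midpoint fractions of their host protein lengths.
#' @param p_threshold homology significance threshold.
#' @param seed RNG seed for the homology test.
#' @return list (`hes_candidate`) with the pair, the similarity score and
#'   empirical p, `positionally_equivalent`, `in_locus` and `verdict`.
#' @export
validate_hes <- function(gs, candidate,
                         homology_test = test_segment_homology,
                         position_tolerance = 0.10, p_threshold = 0.005,
                         seed = 1L) {
  sa <- exon_protein_segment(gs, candidate$host_a, candidate$exon_a)
  sb <- exon_protein_segment(gs, candidate$host_b, candidate$exon_b)
  fail <- function(reason) structure(
    list(candidate = candidate, score = NA_real_, empirical_p = NA_real_,
         positionally_equivalent = FALSE, in_locus = FALSE,
         verdict = FALSE, reason = reason), class = "hes_candidate")
  if (is.null(sa) || is.null(sb)) return(fail("untranslatable exon"))

  # locus guard: both exons inside the span of the gene's other exons
  ids <- gs_isoforms_of(gs, candidate$gene_id)
  ex <- gs$exons[gs$exons$isoform_id %in% ids, , drop = FALSE]
  ex$key <- paste0(ex$chrom, ":", ex$start, "-", ex$end, ":", ex$strand)
  rest <- ex[!ex$key %in% c(candidate$exon_a, candidate$exon_b), , drop = FALSE]
  in_locus <- TRUE
  if (nrow(rest)) {
    locus <- c(min(rest$start), max(rest$end))
    margin <- max(10000L, locus[2] - locus[1])
    for (key in c(candidate$exon_a, candidate$exon_b)) {
      p <- strsplit(key, "[:-]")[[1]]
      dist <- max(0L, locus[1] - as.integer(p[3]),
                  as.integer(p[2]) - locus[2])
      if (p[1] != rest$chrom[1] || dist > margin) in_locus <- FALSE
    }
  }

  h <- homology_test(sa$seq, sb$seq, seed = seed)
  la <- nchar(gs_protein(gs, candidate$host_a))
  lb <- nchar(gs_protein(gs, candidate$host_b))
  mid_a <- (sa$start + sa$end) / 2 / la
  mid_b <- (sb$start + sb$end) / 2 / lb
  pos_eq <- abs(mid_a - mid_b) <= position_tolerance
  homologous <- isTRUE(h$homologous) &&
    (is.na(h$empirical_p) || h$empirical_p <= p_threshold)
  structure(list(candidate = candidate, score = h$score,
                 empirical_p = h$empirical_p,
                 positionally_equivalent = pos_eq, in_locus = in_locus,
                 verdict = homologous && pos_eq && in_locus,
                 reason = NA_character_),
            class = "hes_candidate")
}

#' @export
print.hes_candidate <- function(x, ...) {
  cat(sprintf("HES candidate %s %s | %s: verdict=%s (p=%.4g, pos_eq=%s)\n",
              x$candidate$gene_id, x$candidate$exon_a, x$candidate$exon_b,
              x$verdict, x$empirical_p, x$positionally_equivalent))
  invisible(x)
}

#' Scan a gene_set for homologous exon substitutions
#'
#' Runs [find_mutually_exclusive_pairs()] and [validate_hes()] over every
#' multi-isoform gene.
#'
#' @inheritParams validate_hes
#' @inheritParams find_mutually_exclusive_pairs
#' @return data.frame with one row per candidate pair and its verdict.
#' @export
scan_hes <- function(gs, reference_rule = "longest", min_cds_bp = 30L,
                     homology_test = test_segment_homology,
                     position_tolerance = 0.10, p_threshold = 0.005,
                     seed = 1L) {
  rows <- list()
  for (g in gs_gene_ids(gs)) {
    cands <- find_mutually_exclusive_pairs(gs, g, reference_rule, min_cds_bp)
    for (i in seq_len(nrow(cands))) {
      v <- validate_hes(gs, cands[i, ], homology_test, position_tolerance,
                        p_threshold, seed)
      rows[[length(rows) + 1L]] <- cbind(
        cands[i, ],
        data.frame(score = v$score, empirical_p = v$empirical_p,
                   positionally_equivalent = v$positionally_equivalent,
                   in_locus = v$in_locus, verdict = v$verdict,
                   stringsAsFactors = FALSE))
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(), exon_a = character(),
                      exon_b = character(), host_a = character(),
                      host_b = character(), score = numeric(),
                      empirical_p = numeric(),
                      positionally_equivalent = logical(),
                      in_locus = logical(), verdict = logical(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
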