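#' Project two isoforms of a gene onto each other
#'
#' Protein positions of the two isoforms are matched when they are encoded
#' by the same genomic codon read in the same frame (codon coordinates are
#' taken from the CDS exon chains). Shared genomic sequence translated in a
#' different frame therefore stays unmatched and is treated as substituted
#' sequence. When CDS coordinates are unavailable for either isoform the
#' projection falls back to a global protein alignment, with aligned
#' identical residues counted as matched.
#'
#' @param gs a [gene_set()].
#' @param main_id,alt_id isoform ids of the same gene.
#' @return list with elements `main_len`, `alt_len`, `pairs` (two-column
#'   integer matrix of matched 1-based positions, ascending) and `method`
#'   (`"codon"` or `"alignment"`).
#' @export
project_isoform_pair <- function(gs, main_id, alt_id) {
  if (!identical(gs_gene_of(gs, main_id), gs_gene_of(gs, alt_id)))
    stop("isoforms ", main_id, " and ", alt_id, " belong to different genes",
         call. = FALSE)
  p_main <- gs_protein(gs, main_id)
  p_alt <- gs_protein(gs, alt_id)
  km <- codon_keys(gs, main_id)
  ka <- codon_keys(gs, alt_id)
  if (!is.null(km) && !is.null(ka) && length(km) && length(ka)) {
    km <- km[seq_len(min(length(km), nchar(p_main)))]
    ka <- ka[seq_len(min(length(ka), nchar(p_alt)))]
    j <- match(km, ka)
    i <- which(!is.na(j))
    j <- j[i]
    # keep a monotone chain (codon order is collinear for one gene; guard
    # against pathological duplicates)
    if (length(i) > 1L) {
      keep <- c(TRUE, diff(j) > 0L)
      while (!all(keep)) {
        i <- i[keep]; j <- j[keep]
        keep <- c(TRUE, diff(j) > 0L)
      }
    }
    return(list(main_len = nchar(p_main), alt_len = nchar(p_alt),
                pairs = cbind(i = i, j = j), method = "codon"))
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(canonical_il(p_main)),
    Biostrings::AAString(canonical_il(p_alt)),
    type = "global", substitutionMatrix = blosum62(),
    gapOpening = 10, gapExtension = 0.5)
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  i <- cumsum(a != "-")
  j <- cumsum(b != "-")
  m <- a != "-" & b != "-" & a == b
  list(main_len = nchar(p_main), alt_len = nchar(p_alt),
       pairs = cbind(i = i[m], j = j[m]), method = "alignment")
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

#' Extract splice events between a main and an alternative isoform
#'
#' Maximal runs of unmatched protein positions in the pairwise projection
#' become events: a main-only run is a deletion in the alternative, an
#' alt-only run an insertion, adjacent runs on both sides a substitution.
#' Isoform pairs sharing no matched position yield a single whole-protein
#' event (a candidate two-protein pair). Alternative proteins that are
#' exact prefixes or suffixes of the main protein are treated as
#' truncations and emit no events.
#'
#' @param gs a [gene_set()].
#' @param main_id,alt_id isoform ids of one gene.
#' @param proj optional precomputed [project_isoform_pair()] result.
#' @return list of `splice_event` objects (untyped; see [classify_event()]).
#' @export
extract_events <- function(gs, main_id, alt_id, proj = NULL) {
  p_main <- gs_protein(gs, main_id)
  p_alt <- gs_protein(gs, alt_id)
  if (identical(p_main, p_alt)) return(list())
  cm <- canonical_il(p_main); ca <- canonical_il(p_alt)
  if (nchar(ca) < nchar(cm) &&
      (identical(substr(cm, 1L, nchar(ca)), ca) ||
       identical(substr(cm, nchar(cm) - nchar(ca) + 1L, nchar(cm)), ca)))
    return(list())  # pure truncation of the main isoform
  if (is.null(proj)) proj <- project_isoform_pair(gs, main_id, alt_id)
  n <- proj$main_len; m <- proj$alt_len
  gene_id <- gs_gene_of(gs, main_id)

  mk_event <- function(ms, me, as, ae, no_match = FALSE) {
    main_seg <- if (me >= ms) c(ms, me) else NULL
    alt_seg <- if (ae >= as) c(as, ae) else NULL
    ev <- list(gene_id = gene_id, main_isoform_id = main_id,
               alt_isoform_id = alt_id,
               main_segment = main_seg, alt_segment = alt_seg,
               main_len = n, alt_len = m,
               main_seq = if (!is.null(main_seg)) substr(p_main, ms, me) else "",
               alt_seq = if (!is.null(alt_seg)) substr(p_alt, as, ae) else "",
               main_flank = c(ms - 1L, me + 1L),
               alt_flank = c(as - 1L, ae + 1L),
               no_match = no_match, kind = NA_character_,
               homology_score = NA_real_, empirical_p = NA_real_)
    ev$genomic_key <- event_genomic_key(gs, ev)
    class(ev) <- "splice_event"
    ev
  }

  pairs <- proj$pairs
  if (!nrow(pairs))
    return(list(mk_event(1L, n, 1L, m, no_match = TRUE)))
  i <- c(0L, pairs[, 1L], n + 1L)
  j <- c(0L, pairs[, 2L], m + 1L)
  out <- list()
  for (k in seq_len(length(i) - 1L)) {
    gap_m <- i[k + 1L] - i[k] - 1L
    gap_a <- j[k + 1L] - j[k] - 1L
    if (gap_m > 0L || gap_a > 0L)
      out[[length(out) + 1L]] <-
        mk_event(i[k] + 1L, i[k + 1L] - 1L, j[k] + 1L, j[k + 1L] - 1L)
  }
  out
}

# Deduplication key: genomic span of the unmatched codons on both sides
# (falls back to the segment sequences when no CDS coordinates exist).
event_genomic_key <- function(gs, ev) {
  cc <- cds_nt_coords(gs, ev$main_isoform_id)
  ca <- cds_nt_coords(gs, ev$alt_isoform_id)
  if (is.null(cc) || is.null(ca))
    return(paste0("seq|", ev$main_seq, "|", ev$alt_seq))
  span <- function(cc, seg) {
    if (is.null(seg)) return("-")
    nt <- cc$pos[(3L * seg[1] - 2L):min(3L * seg[2], length(cc$pos))]
    paste0(min(nt), "-", max(nt))
  }
  paste0(cc$chrom, cc$strand, "|", span(cc, ev$main_segment), "|",
         span(ca, ev$alt_segment))
}

#' @export
print.splice_event <- function(x, ...) {
  seg <- function(s) if (is.null(s)) "-" else paste0(s[1], "..", s[2])
  cat(sprintf("splice_event [%s] %s: %s (%s) vs %s (%s)\n",
              x$kind %||% "untyped", x$gene_id,
              x$main_isoform_id, seg(x$main_segment),
              x$alt_isoform_id, seg(x$alt_segment)))
  invisible(x)
}

#' Permutation test for segment homology
#'
#' Scores a local alignment (BLOSUM62, affine gaps) between two protein
#' segments and assesses significance against scores of shuffled versions
#' of the second segment. The empirical p-value has floor 1/(n_shuffle+1),
#' so the default 200 shuffles can just reach the 0.005 threshold: calling
#' two segments homologous requires the observed score to beat every
#' shuffle.
#'
#' @param segA,segB amino-acid segments (length >= 2).
#' @param n_shuffle number of shuffles for the permutation null.
#' @param p_threshold call threshold on the empirical p-value.
#' @param seed RNG seed for the shuffles (restored afterwards).
#' @return list with `homologous`, `score`, `empirical_p`.
#' @export
test_segment_homology <- function(segA, segB, n_shuffle = 200L,
                                  p_threshold = 0.005, seed = 1L) {
  if (nchar(segA) < 2L || nchar(segB) < 2L)
    return(list(homologous = FALSE, score = NA_real_,
                empirical_p = NA_real_))
  mat <- blosum62()
  a <- Biostrings::AAString(segA)
  obs <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(segB), a, type = "local",
    substitutionMatrix = mat, gapOpening = 10, gapExtension = 1,
    scoreOnly = TRUE)
  chars <- strsplit(segB, "", fixed = TRUE)[[1]]
  shuffled <- with_seed(seed, vapply(seq_len(n_shuffle), function(k)
    paste(sample(chars), collapse = ""), character(1)))
  null_scores <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(shuffled), a, type = "local",
    substitutionMatrix = mat, gapOpening = 10, gapExtension = 1,
    scoreOnly = TRUE)
  p <- (1 + sum(null_scores >= obs)) / (n_shuffle + 1)
  list(homologous = p <= p_threshold, score = obs, empirical_p = p)
}

#' Classify a splice event
#'
#' Assigns exactly one of the seven event kinds:
#' `two_proteins` (no matched positions at all), `nagnag` (pure indel of at
#' most 4 residues), `indel` (pure indel of more than 4),
#' `homologous_substitution` (both segments present and significantly
#' homologous), `nterm_substitution` / `cterm_substitution`
#' (non-homologous substitution touching the first / last protein
#' position; when both termini are touched the longer unmatched terminus
#' decides), and `internal_substitution` otherwise.
#'
#' @param event a `splice_event` from [extract_events()].
#' @param homology_test function(segA, segB, seed) used for substitutions;
#'   defaults to [test_segment_homology()].
#' @param seed passed to the homology test.
#' @return The kind as a character scalar, with the homology score and
#'   empirical p (when computed) as attributes.
#' @export
classify_event <- function(event, homology_test = test_segment_homology,
                           seed = 1L) {
  if (event$no_match) return("two_proteins")
  lm <- if (is.null(event$main_segment)) 0L else
    event$main_segment[2] - event$main_segment[1] + 1L
  la <- if (is.null(event$alt_segment)) 0L else
    event$alt_segment[2] - event$alt_segment[1] + 1L
  if (lm == 0L || la == 0L) {                     # pure insertion/deletion
    return(if (max(lm, la) <= 4L) "nagnag" else "indel")
  }
  h <- list(homologous = FALSE, score = NA_real_, empirical_p = NA_real_)
  if (lm >= 2L && la >= 2L)
    h <- homology_test(event$main_seq, event$alt_seq, seed = seed)
  if (isTRUE(h$homologous)) {
    out <- "homologous_substitution"
  } else {
    t_n <- event$main_segment[1] == 1L || event$alt_segment[1] == 1L
    t_c <- event$main_segment[2] == event$main_len ||
      event$alt_segment[2] == event$alt_len
    out <- if (t_n && t_c) {
      ext_n <- max(if (event$main_segment[1] == 1L) event$main_segment[2] else 0L,
                   if (event$alt_segment[1] == 1L) event$alt_segment[2] else 0L)
      ext_c <- max(if (event$main_segment[2] == event$main_len)
                     event$main_len - event$main_segment[1] + 1L else 0L,
                   if (event$alt_segment[2] == event$alt_len)
                     event$alt_len - event$alt_segment[1] + 1L else 0L)
      if (ext_n >= ext_c) "nterm_substitution" else "cterm_substitution"
    } else if (t_n) "nterm_substitution"
    else if (t_c) "cterm_substitution"
    else "internal_substitution"
  }
  attr(out, "score") <- h$score
  attr(out, "empirical_p") <- h$empirical_p
  out
}

# classify a list of events in place
classify_events <- function(events, homology_test = test_segment_homology,
                            seed = 1L) {
  lapply(events, function(ev) {
    k <- classify_event(ev, homology_test, seed)
    ev$kind <- as.character(k)
    ev$homology_score <- attr(k, "score") %||% NA_real_
    ev$empirical_p <- attr(k, "empirical_p") %||% NA_real_
    ev
  })
}

#' Detect peptide evidence on both sides of a splice event
#'
#' For an inserted or substituted segment, any peptide specific to that
#' isoform (within the pair) overlapping the segment by at least one
#' residue counts as evidence. For the side where sequence was deleted, a
#' peptide on the shorter isoform must span the junction with at least one
#' residue on each flank. An identified splicing event (ISE) requires
#' evidence on both sides.
#'
#' @param event a classified `splice_event`.
#' @param matches a `peptide_matches` object for the gene.
#' @return An `ise` object (event plus the supporting peptide sets), or
#'   `NULL` when either side lacks evidence.
#' @export
detect_ise <- function(event, matches) {
  m <- matches[matches$gene_id == event$gene_id, , drop = FALSE]
  on_iso <- function(iso) unique(m$canon_seq[m$isoform_id == iso])
  main_peps <- setdiff(on_iso(event$main_isoform_id),
                       on_iso(event$alt_isoform_id))
  alt_peps <- setdiff(on_iso(event$alt_isoform_id),
                      on_iso(event$main_isoform_id))

  side_support <- function(peps, iso, seg, flank, prot_len) {
    if (!length(peps)) return(character())
    keep <- vapply(peps, function(p) {
      starts <- match_positions(m, iso, p)
      len <- nchar(p)
      if (!is.null(seg)) {
        any(starts <= seg[2] & (starts + len - 1L) >= seg[1])
      } else {
        # deleted side: junction between flank[1] and flank[2] (= flank[1]+1)
        jl <- flank[1]
        if (jl < 1L || jl + 1L > prot_len) return(FALSE)
        any(starts <= jl & (starts + len - 1L) >= jl + 1L)
      }
    }, logical(1))
    peps[keep]
  }

  main_sup <- side_support(main_peps, event$main_isoform_id,
                           event$main_segment, event$main_flank,
                           event$main_len)
  alt_sup <- side_support(alt_peps, event$alt_isoform_id,
                          event$alt_segment, event$alt_flank,
                          event$alt_len)
  if (!length(main_sup) || !length(alt_sup)) return(NULL)
  structure(list(event = event, main_side_peptides = main_sup,
                 alt_side_peptides = alt_sup), class = "ise")
}

#' @export
print.ise <- function(x, ...) {
  cat(sprintf("ISE [%s] %s: %d + %d supporting peptides\n",
              x$event$kind, x$event$gene_id,
              length(x$main_side_peptides), length(x$alt_side_peptides)))
  invisible(x)
}

#' Collapse duplicate splice events
#'
#' Events with identical (gene, kind, genomic key) — e.g. the same exon
#' skip seen in several isoform pairs — collapse to one record.
#'
#' @param events list of classified `splice_event`s.
#' @return The unique sub-list, first occurrence kept.
#' @export
dedupe_events <- function(events) {
  if (!length(events)) return(events)
  keys <- vapply(events, function(e)
    paste(e$gene_id, e$kind, e$genomic_key, sep = "\r"), character(1))
  events[!duplicated(keys)]
}

#' Convert a list of splice events to a data.frame
#' @param events list of `splice_event`s.
#' @return data.frame with one row per event.
#' @export
events_table <- function(events) {
  if (!length(events))
    return(data.frame(gene_id = character(), main_isoform_id = character(),
                      alt_isoform_id = character(), kind = character(),
                      main_start = integer(), main_end = integer(),
                      alt_start = integer(), alt_end = integer(),
                      genomic_key = character(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(events, function(e) data.frame(
    gene_id = e$gene_id, main_isoform_id = e$main_isoform_id,
    alt_isoform_id = e$alt_isoform_id, kind = e$kind,
    main_start = if (is.null(e$main_segment)) NA_integer_ else e$main_segment[1],
    main_end = if (is.null(e$main_segment)) NA_integer_ else e$main_segment[2],
    alt_start = if (is.null(e$alt_segment)) NA_integer_ else e$alt_segment[1],
    alt_end = if (is.null(e$alt_segment)) NA_integer_ else e$alt_segment[2],
    genomic_key = e$genomic_key, stringsAsFactors = FALSE)))
}
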