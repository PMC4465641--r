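#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test. The two-sided p-value sums, over all tables
#' with the observed margins, the probabilities no larger than that of the
#' observed table (minimum-likelihood summation). The odds ratio is the
#' sample odds ratio `(a*d)/(b*c)`, with 0.5 added to every cell when any
#' cell is zero.
#'
#' @param a,b,c,d cell counts: rows are in-set/background, columns
#'   detected/not detected.
#' @param sided `"two"` (default), `"greater"` or `"less"` (on the `a`
#'   cell).
#' @return list with `p_value` and `odds_ratio`.
#' @export
fisher_exact <- function(a, b, c, d, sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    stop("fisher_exact: zero margin", call. = FALSE)
  m <- a + b          # size of set 1
  n <- c + d          # size of set 2
  k <- a + c          # total detected
  lo <- max(0L, k - n)
  hi <- min(k, m)
  x <- lo:hi
  probs <- stats::dhyper(x, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- switch(sided,
              two = sum(probs[probs <= p_obs * (1 + 1e-7)]),
              greater = sum(probs[x >= a]),
              less = sum(probs[x <= a]))
  cells <- c(a, b, c, d)
  if (any(cells == 0)) cells <- cells + 0.5
  list(p_value = min(1, p),
       odds_ratio = (cells[1] * cells[4]) / (cells[2] * cells[3]))
}

#' Assign cross-species similarity hits to genes
#'
#' Hits within a species-specific distance window of an annotated gene are
#' assigned to that gene; the window is the given quantile (default the
#' 95th percentile) of the species' gene lengths. Remaining hits are
#' clustered into new loci by single linkage under the same window.
#'
#' @param hits data.frame with columns `hit_id`, `chrom`, `start`, `end`
#'   (and optionally `species`).
#' @param target_genes data.frame with columns `gene_id`, `chrom`,
#'   `start`, `end`.
#' @param gene_lengths numeric vector of gene lengths in the target
#'   species (used for the window); defaults to the lengths of
#'   `target_genes`.
#' @param window_quantile quantile of gene lengths defining the window.
#' @return data.frame with columns `hit_id`, `assigned` (gene id or
#'   `new_locus_<k>`).
#' @export
assign_hits_to_genes <- function(hits, target_genes, gene_lengths = NULL,
                                 window_quantile = 0.95) {
  if (is.null(gene_lengths))
    gene_lengths <- target_genes$end - target_genes$start
  window <- as.numeric(stats::quantile(gene_lengths, window_quantile))
  assigned <- rep(NA_character_, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    same <- target_genes$chrom == hits$chrom[i]
    if (!any(same)) next
    gaps <- pmax(0, pmax(target_genes$start[same] - hits$end[i],
                         hits$start[i] - target_genes$end[same]))
    j <- which(gaps <= window)
    if (length(j))
      assigned[i] <- target_genes$gene_id[same][j[which.min(gaps[j])]]
  }
  # cluster unassigned hits into new loci: single linkage within window
  un <- which(is.na(assigned))
  if (length(un)) {
    k <- 0L
    for (chr in unique(hits$chrom[un])) {
      idx <- un[hits$chrom[un] == chr]
      idx <- idx[order(hits$start[idx])]
      locus_end <- -Inf
      for (i in idx) {
        if (hits$start[i] - locus_end > window) k <- k + 1L
        assigned[i] <- paste0("new_locus_", k)
        locus_end <- max(locus_end, hits$end[i])
      }
    }
  }
  data.frame(hit_id = hits$hit_id, assigned = assigned,
             stringsAsFactors = FALSE)
}

#' Dollo-parsimony origin of a presence/absence character
#'
#' Under Dollo parsimony (a character is gained once and may be lost many
#' times) the origin of a feature is the most recent common ancestor of
#' the taxa possessing it; absences below that node are losses.
#'
#' @param tree a rooted `phylo` tree (see [ape::read.tree()]).
#' @param presence named logical vector over tree tip labels (or a
#'   character vector of present tips).
#' @return list with `node` (ape node number; for a single present tip the
#'   tip number), `label` (`node label` or tip label when available) and
#'   `present_tips`.
#' @export
dollo_origin <- function(tree, presence) {
  tips <- if (is.logical(presence)) names(presence)[presence]
          else as.character(presence)
  if (!length(tips)) stop("no present taxa", call. = FALSE)
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown))
    stop("presence names not in tree: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (length(tips) == 1L) {
    node <- match(tips, tree$tip.label)
    return(list(node = node, label = tips, present_tips = tips))
  }
  node <- ape::getMRCA(tree, tips)
  lab <- if (!is.null(tree$node.label)) {
    l <- tree$node.label[node - ape::Ntip(tree)]
    if (is.na(l) || !nzchar(l)) NA_character_ else l
  } else NA_character_
  list(node = node, label = lab, present_tips = sort(tips))
}

#' Fraction of exons conserved across species
#'
#' @param conserved logical vector (or named logical) of per-exon
#'   conservation calls.
#' @return The conserved fraction in `[0, 1]`.
#' @export
conservation_fraction <- function(conserved) {
  if (!length(conserved)) stop("empty conservation input", call. = FALSE)
  mean(as.logical(conserved))
}
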