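#' Peptide weights under a null abundance model
#'
#' Under the uniform model every unique peptide of a gene has weight 1
#' (all isoforms expressed equally). Under the dominant model the
#' principal isoform is expressed `ratio` times more than each other
#' isoform, so a peptide's weight aggregates the abundances of the
#' isoforms containing it: `ratio * [occurs in principal] + (number of
#' non-principal isoforms containing it)`.
#'
#' @param db a `peptide_db` (see [build_peptide_db()]).
#' @param gs a [gene_set()] with principal flags set.
#' @param gene_id gene whose peptides are weighted.
#' @param model `"uniform"` or `"dominant"`.
#' @param ratio dominance ratio (default 50).
#' @return named numeric vector of weights over the gene's unique
#'   peptides.
#' @export
assign_peptide_weights <- function(db, gs, gene_id,
                                   model = c("uniform", "dominant"),
                                   ratio = 50) {
  model <- match.arg(model)
  stopifnot(ratio >= 1)
  d <- db[db$gene_id == gene_id, , drop = FALSE]
  if (!nrow(d)) stop("gene absent from peptide db: ", gene_id, call. = FALSE)
  peps <- unique(d$canon_seq)
  if (model == "uniform")
    return(stats::setNames(rep(1, length(peps)), peps))
  iso <- gs$isoforms[gs$isoforms$gene_id == gene_id, , drop = FALSE]
  prin <- iso$isoform_id[iso$principal]
  if (!length(prin)) prin <- select_principal(gs, gene_id)
  w <- vapply(peps, function(p) {
    isos <- unique(d$isoform_id[d$canon_seq == p])
    ratio * as.numeric(prin[1] %in% isos) + sum(isos != prin[1])
  }, numeric(1))
  w
}

# Event side-support sets computed over the peptide universe of a
# peptide_db: which db peptides could evidence each side of each
# main-vs-alternative event of a gene. Reuses the both-sides rule of
# detect_ise (segment overlap for inserted/substituted sequence, junction
# spanning for deletions).
gene_event_support <- function(gs, gene_id, db) {
  iso <- gs$isoforms[gs$isoforms$gene_id == gene_id, , drop = FALSE]
  if (nrow(iso) < 2L) return(list())
  prin <- iso$isoform_id[iso$principal]
  main_id <- if (length(prin)) prin[1] else select_principal(gs, gene_id)
  d <- db[db$gene_id == gene_id, , drop = FALSE]
  if (!nrow(d)) return(list())
  iso_sets <- split(d$canon_seq, d$isoform_id)
  starts_of <- function(isoform, pep)
    d$start[d$isoform_id == isoform & d$canon_seq == pep]

  support <- function(peps, isoform, seg, flank, prot_len) {
    if (!length(peps)) return(character())
    keep <- vapply(peps, function(p) {
      st <- starts_of(isoform, p)
      len <- nchar(p)
      if (!is.null(seg)) any(st <= seg[2] & st + len - 1L >= seg[1])
      else {
        jl <- flank[1]
        jl >= 1L && jl + 1L <= prot_len &&
          any(st <= jl & st + len - 1L >= jl + 1L)
      }
    }, logical(1))
    peps[keep]
  }

  out <- list()
  for (alt_id in setdiff(iso$isoform_id, main_id)) {
    evs <- extract_events(gs, main_id, alt_id)
    main_set <- iso_sets[[main_id]] %||% character()
    alt_set <- iso_sets[[alt_id]] %||% character()
    for (ev in evs) {
      ms <- support(setdiff(unique(main_set), alt_set), main_id,
                    ev$main_segment, ev$main_flank, ev$main_len)
      as_ <- support(setdiff(unique(alt_set), main_set), alt_id,
                     ev$alt_segment, ev$alt_flank, ev$alt_len)
      if (length(ms) && length(as_))
        out[[length(out) + 1L]] <- list(alt_isoform_id = alt_id,
                                        main_sup = ms, alt_sup = as_)
    }
  }
  out
}

#' Simulate peptide draws under a null abundance model
#'
#' For each replicate and each gene, draws the observed number of peptides
#' for that gene from the in-silico tryptic peptide database, without
#' replacement, with probability proportional to the model weight. A gene
#' counts as an AS gene in a replicate when the drawn set provides
#' both-sides evidence for at least one event between its main isoform
#' and any alternative; it counts towards the three-or-more-isoform tally
#' when at least two distinct alternative isoforms are evidenced.
#'
#' @param gs a [gene_set()] with principal flags set.
#' @param db a `peptide_db` of fully tryptic peptides.
#' @param per_gene_counts named integer vector: peptides to draw per gene
#'   (typically the observed per-gene peptide counts).
#' @param model,ratio see [assign_peptide_weights()].
#' @param replicates number of Monte-Carlo replicates.
#' @param seed RNG seed; a fixed seed gives bit-identical output.
#' @return A `simulation_summary`: list with `per_replicate` (data.frame
#'   of `as_genes`, `three_plus_genes`), `mean_as_genes`,
#'   `mean_three_plus_genes`, `model`, `ratio`, `replicates`.
#' @export
simulate_draws <- function(gs, db, per_gene_counts,
                           model = c("uniform", "dominant"), ratio = 50,
                           replicates = 100L, seed = 1L) {
  model <- match.arg(model)
  stopifnot(replicates >= 1L)
  genes <- names(per_gene_counts)
  genes <- genes[genes %in% db$gene_id & per_gene_counts[genes] > 0L]

  prep <- list()
  overdrawn <- character()
  for (g in genes) {
    sup <- gene_event_support(gs, g, db)
    w <- assign_peptide_weights(db, gs, g, model, ratio)
    peps <- names(w)
    k <- per_gene_counts[[g]]
    if (k > length(peps)) { overdrawn <- c(overdrawn, g); k <- length(peps) }
    if (!length(sup)) next  # no detectable event for this gene
    sup_idx <- lapply(sup, function(s)
      list(alt = s$alt_isoform_id,
           main_sup = match(s$main_sup, peps),
           alt_sup = match(s$alt_sup, peps)))
    prep[[g]] <- list(n = length(peps), w = unname(w), k = as.integer(k),
                      sup = sup_idx)
  }
  if (length(overdrawn))
    warning("draw count exceeds unique peptides for ", length(overdrawn),
            " gene(s); drawing all", call. = FALSE)

  res <- with_seed(seed, {
    as_genes <- integer(replicates)
    three_plus <- integer(replicates)
    for (r in seq_len(replicates)) {
      n_as <- 0L; n_three <- 0L
      for (g in names(prep)) {
        pg <- prep[[g]]
        drawn <- if (pg$k >= pg$n) seq_len(pg$n)
                 else sample.int(pg$n, pg$k, prob = pg$w)
        alts <- character()
        for (s in pg$sup) {
          if (any(s$main_sup %in% drawn) && any(s$alt_sup %in% drawn))
            alts <- c(alts, s$alt)
        }
        if (length(alts)) n_as <- n_as + 1L
        if (length(unique(alts)) >= 2L) n_three <- n_three + 1L
      }
      as_genes[r] <- n_as
      three_plus[r] <- n_three
    }
    data.frame(as_genes = as_genes, three_plus_genes = three_plus)
  })
  structure(list(per_replicate = res,
                 mean_as_genes = mean(res$as_genes),
                 mean_three_plus_genes = mean(res$three_plus_genes),
                 model = model, ratio = ratio,
                 replicates = as.integer(replicates)),
            class = "simulation_summary")
}

#' @export
print.simulation_summary <- function(x, ...) {
  cat(sprintf("null-model simulation (%s%s, %d replicates)\n",
              x$model,
              if (x$model == "dominant") sprintf(" %g:1", x$ratio) else "",
              x$replicates))
  cat(sprintf("  mean AS genes:            %.1f\n", x$mean_as_genes))
  cat(sprintf("  mean >=3-isoform genes:   %.1f\n", x$mean_three_plus_genes))
  invisible(x)
}

#' Fold change of simulated over observed AS detection
#'
#' @param summary a `simulation_summary`.
#' @param observed list or named vector with `as_genes` and
#'   `three_plus_genes` observed counts.
#' @return list with `as_gene_ratio`, `three_plus_ratio` and `infinite`
#'   flags for zero observed baselines.
#' @export
compare_to_observed <- function(summary, observed) {
  obs_as <- observed[["as_genes"]]
  obs_3 <- observed[["three_plus_genes"]]
  r1 <- if (obs_as == 0) Inf else summary$mean_as_genes / obs_as
  r2 <- if (obs_3 == 0) Inf else summary$mean_three_plus_genes / obs_3
  list(as_gene_ratio = r1, three_plus_ratio = r2,
       infinite = c(as_genes = !is.finite(r1), three_plus = !is.finite(r2)))
}
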