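# Simulated multi-experiment peptide detections over a synthetic gene set,
# with labelled filter-target artifacts and generator-side expectations.

#' Default per-dataset filter configurations for the simulated experiments
#'
#' Eight heterogeneous experiments: three score-thresholded single-engine
#' sets (Andromeda-like, score >= 100), two two-engine intersection sets
#' (Mascot/Sequest-like), two FDR-filtered single-engine sets with no extra
#' per-dataset rule, and one multi-engine compendium requiring agreement of
#' two engines (NIST-like).
#'
#' @param n_experiments number of datasets (default 8; fewer uses a prefix).
#' @return named list of [dataset_filter_config()].
#' @export
default_dataset_configs <- function(n_experiments = 8L) {
  mk <- function(id, ...) dataset_filter_config(id, ...)
  all <- list(
    ds1 = mk("ds1", min_score = 100),
    ds2 = mk("ds2", min_score = 100),
    ds3 = mk("ds3", min_score = 100),
    ds4 = mk("ds4", min_engines = 2L),
    ds5 = mk("ds5", min_engines = 2L),
    ds6 = mk("ds6"),
    ds7 = mk("ds7"),
    ds8 = mk("ds8", min_engines = 2L))
  all[seq_len(min(n_experiments, length(all)))]
}

dataset_engines <- function(ds) {
  switch(ds,
         ds1 = , ds2 = , ds3 = "andromeda",
         ds4 = , ds5 = "mascot;sequest",
         ds6 = "xtandem",
         ds7 = "mascot",
         ds8 = paste(sample(c("sequest", "andromeda", "mascot", "xtandem",
                              "omssa"), sample(2:4, 1L)), collapse = ";"),
         "engineA")
}

dataset_score <- function(ds, good = TRUE) {
  if (ds %in% c("ds1", "ds2", "ds3"))
    return(if (good) 100 + stats::rexp(1, 1 / 80) else stats::runif(1, 20, 95))
  round(stats::runif(1, 20, 400), 1)
}

#' Simulate per-experiment peptide detections with injected artifacts
#'
#' Digests every isoform (trypsin, up to one missed cleavage, >= 7
#' residues), assigns each gene a log-normal abundance split across its
#' isoforms at the dominance ratio (the principal isoform `ratio` times
#' each alternative), samples detections independently per experiment with
#' probability increasing in peptide abundance, and injects four classes
#' of labelled artifacts: non-tryptic substrings, missed-cleavage peptides
#' without their fully cleaved sub-peptides, single-experiment peptides,
#' and sub-threshold scores. Missed-cleavage detections are only emitted
#' in a dataset when a fully cleaved sub-peptide is emitted there too.
#'
#' @param synth output of [generate_gene_set()].
#' @param n_experiments number of datasets (see
#'   [default_dataset_configs()]).
#' @param dominance_ratio within-gene abundance ratio of the principal
#'   isoform over each alternative.
#' @param abund_meanlog,abund_sdlog log-normal gene abundance parameters.
#' @param detect_scale per-experiment detection rate scale: a peptide of
#'   abundance `a` is detected with probability `1 - exp(-detect_scale*a)`.
#' @param missed_detect_factor detectability multiplier for missed-
#'   cleavage peptides.
#' @param artifact_rates named rates (fraction of clean record count) for
#'   `non_tryptic`, `unsupported_missed`, `single_experiment`, `sub_score`.
#' @param seed RNG seed.
#' @return list with `tables` (named list of per-dataset record
#'   data.frames), `configs` (matching filter configs), `truth` (record-
#'   level data.frame with `class` = clean/artifact label), `expected`
#'   (list: `final_canon` — clean canonical peptides in >= 2 datasets;
#'   `detectable_events` — truth events flagged by generator-side
#'   both-sides detectability; `per_gene_tryptic_counts`), and
#'   `gene_set` (the cluster-merged, principal-flagged gene set used).
#' @export
simulate_detections <- function(synth, n_experiments = 8L,
                                dominance_ratio = 50,
                                abund_meanlog = -0.5, abund_sdlog = 1.5,
                                detect_scale = 1.2,
                                missed_detect_factor = 0.3,
                                artifact_rates = c(non_tryptic = 0.01,
                                                   unsupported_missed = 0.01,
                                                   single_experiment = 0.01,
                                                   sub_score = 0.01),
                                seed = 1L) {
  gs <- synth$gene_set
  if (nrow(synth$truth$clusters))
    gs <- merge_gene_clusters(gs, synth$truth$clusters)
  gs <- mark_principal(gs)
  with_seed(seed, simulate_detections_impl(
    gs, synth, n_experiments, dominance_ratio, abund_meanlog, abund_sdlog,
    detect_scale, missed_detect_factor, artifact_rates))
}

simulate_detections_impl <- function(gs, synth, n_experiments,
                                     dominance_ratio, abund_meanlog,
                                     abund_sdlog, detect_scale,
                                     missed_detect_factor, artifact_rates) {
  ds_ids <- names(default_dataset_configs(n_experiments))
  iso <- gs$isoforms[!gs$isoforms$read_through, , drop = FALSE]

  # digest all isoforms (0- and 1-missed)
  digs <- lapply(seq_len(nrow(iso)), function(i) {
    d <- digest_protein(iso$protein[i], "trypsin", max_missed = 1L,
                        min_len = 7L)
    if (!nrow(d)) return(NULL)
    d$isoform_id <- iso$isoform_id[i]
    d$gene_id <- iso$gene_id[i]
    d$prot_len <- nchar(iso$protein[i])
    d
  })
  digs <- do.call(rbind, digs[!vapply(digs, is.null, logical(1))])
  digs$canon <- canonical_il(digs$peptide)
  digs$end <- digs$start + nchar(digs$peptide) - 1L

  # abundance: gene level log-normal, isoform shares at the dominance ratio
  genes <- unique(iso$gene_id)
  A <- stats::setNames(stats::rlnorm(length(genes), abund_meanlog,
                                     abund_sdlog), genes)
  share <- numeric(nrow(iso))
  for (g in genes) {
    sel <- iso$gene_id == g
    n_alt <- sum(sel) - 1L
    pr <- iso$principal[sel]
    sh <- ifelse(pr, dominance_ratio, 1) / (dominance_ratio + n_alt)
    share[sel] <- sh
  }
  names(share) <- iso$isoform_id

  # unique peptide per gene with summed isoform shares
  key <- paste(digs$gene_id, digs$canon, sep = "\r")
  first <- !duplicated(key)
  pep <- digs[first, c("gene_id", "canon", "peptide", "n_missed",
                       "isoform_id", "start", "prot_len")]
  sh_sum <- tapply(share[digs$isoform_id] *
                     !duplicated(paste(key, digs$isoform_id)), key, sum)
  pep$abund <- unname(A[pep$gene_id] * sh_sum[paste(pep$gene_id, pep$canon,
                                                    sep = "\r")])
  pep$p_detect <- (1 - exp(-detect_scale * pep$abund)) *
    ifelse(pep$n_missed > 0L, missed_detect_factor, 1)

  # flanking residues of each representative occurrence (vectorized)
  prot_by_iso <- stats::setNames(iso$protein, iso$isoform_id)
  pp <- unname(prot_by_iso[pep$isoform_id])
  pend <- pep$start + nchar(pep$peptide) - 1L
  pep$prev_aa <- ifelse(pep$start == 1L, "-",
                        substr(pp, pep$start - 1L, pep$start - 1L))
  pep$next_aa <- ifelse(pend == nchar(pp), "-",
                        substr(pp, pend + 1L, pend + 1L))

  # per-peptide missed-cleavage sub-peptides (for within-dataset support)
  sub_canon_of <- lapply(seq_len(nrow(pep)), function(j) {
    if (pep$n_missed[j] == 0L) return(NULL)
    canonical_il(digest_protein(pep$peptide[j], "trypsin", 0L, 7L)$peptide)
  })

  # detection sampling
  tables <- stats::setNames(vector("list", length(ds_ids)), ds_ids)
  truth_rows <- list()
  for (ds in ds_ids) {
    hit <- stats::runif(nrow(pep)) < pep$p_detect
    d <- pep[hit, , drop = FALSE]
    subs_d <- sub_canon_of[hit]
    if (nrow(d)) {
      # missed-cleavage detections need a fully cleaved sub-peptide here
      zero <- unique(d$canon[d$n_missed == 0L])
      keep <- vapply(seq_len(nrow(d)), function(j)
        d$n_missed[j] == 0L || any(subs_d[[j]] %in% zero), logical(1))
      d <- d[keep, , drop = FALSE]
    }
    tab <- if (nrow(d)) data.frame(
      sequence = d$peptide, dataset = ds,
      engines = vapply(seq_len(nrow(d)), function(j) dataset_engines(ds),
                       character(1)),
      score = vapply(seq_len(nrow(d)), function(j)
        dataset_score(ds, good = TRUE), numeric(1)),
      enzyme = "trypsin", n_missed = d$n_missed,
      prev_aa = d$prev_aa, next_aa = d$next_aa,
      stringsAsFactors = FALSE) else empty_peptide_table()
    tables[[ds]] <- tab
    if (nrow(tab))
      truth_rows[[ds]] <- data.frame(dataset = ds, sequence = tab$sequence,
                                     class = "clean",
                                     gene_id = d$gene_id,
                                     stringsAsFactors = FALSE)
  }

  clean_canon_all <- canonical_il(unlist(lapply(tables, function(t) t$sequence),
                                         use.names = FALSE))
  n_clean <- length(clean_canon_all)
  clean_canon_set <- unique(clean_canon_all)

  art <- inject_artifacts(gs, pep, tables, truth_rows, clean_canon_set,
                          artifact_rates, n_clean, ds_ids)
  tables <- art$tables
  truth_rows <- art$truth_rows

  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL

  # expected surviving canonical set: clean peptides in >= 2 datasets
  cl <- truth[truth$class == "clean", , drop = FALSE]
  cl$canon <- canonical_il(cl$sequence)
  nds <- tapply(cl$dataset, cl$canon, function(x) length(unique(x)))
  final_canon <- names(nds)[nds >= 2L]

  detectable <- flag_detectable_events(gs, synth$truth$events, digs,
                                       final_canon)

  # observed per-gene counts of fully tryptic (0-missed) final peptides
  tr0 <- unique(digs[digs$n_missed == 0L, c("gene_id", "canon")])
  tr0 <- tr0[tr0$canon %in% final_canon, , drop = FALSE]
  per_gene <- table(tr0$gene_id)

  list(tables = tables,
       configs = default_dataset_configs(n_experiments),
       truth = truth,
       expected = list(final_canon = sort(final_canon),
                       detectable_events = detectable,
                       per_gene_tryptic_counts =
                         stats::setNames(as.integer(per_gene),
                                         names(per_gene))),
       gene_set = gs)
}

empty_peptide_table <- function() {
  data.frame(sequence = character(), dataset = character(),
             engines = character(), score = numeric(), enzyme = character(),
             n_missed = integer(), prev_aa = character(),
             next_aa = character(), stringsAsFactors = FALSE)
}

# Generator-side truth flags: which planted events could the final clean
# peptide set evidence on both sides? Computed from the truth coordinates
# and digestion positions, independently of the events module.
flag_detectable_events <- function(gs, events_df, digs, final_canon) {
  prot_all <- canonical_il(gs$isoforms$protein)
  names(prot_all) <- gs$isoforms$isoform_id
  uniq_to_gene <- function(canon, gene) {
    others <- prot_all[gs$isoforms$gene_id != gene]
    !any(grepl(canon, others, fixed = TRUE))
  }
  out <- logical(nrow(events_df))
  for (i in seq_len(nrow(events_df))) {
    ev <- events_df[i, ]
    dm <- digs[digs$isoform_id == ev$main_isoform_id, , drop = FALSE]
    da <- digs[digs$isoform_id == ev$alt_isoform_id, , drop = FALSE]
    if (!nrow(dm) || !nrow(da)) next
    p_alt <- prot_all[[ev$alt_isoform_id]]
    p_main <- prot_all[[ev$main_isoform_id]]
    # main side: overlap the main segment, absent from the alt protein
    cand_m <- dm[dm$start <= ev$main_end & dm$end >= ev$main_start, ,
                 drop = FALSE]
    ok_m <- FALSE
    for (j in seq_len(nrow(cand_m))) {
      cn <- cand_m$canon[j]
      if (cn %in% final_canon && !grepl(cn, p_alt, fixed = TRUE) &&
          uniq_to_gene(cn, ev$gene_id)) { ok_m <- TRUE; break }
    }
    if (!ok_m) next
    # alt side: segment overlap, or junction spanning for deletions
    if (!is.na(ev$alt_start)) {
      cand_a <- da[da$start <= ev$alt_end & da$end >= ev$alt_start, ,
                   drop = FALSE]
    } else {
      jl <- ev$alt_junction
      cand_a <- da[da$start <= jl & da$end >= jl + 1L, , drop = FALSE]
    }
    ok_a <- FALSE
    for (j in seq_len(nrow(cand_a))) {
      cn <- cand_a$canon[j]
      if (cn %in% final_canon && !grepl(cn, p_main, fixed = TRUE) &&
          uniq_to_gene(cn, ev$gene_id)) { ok_a <- TRUE; break }
    }
    out[i] <- ok_a
  }
  cbind(events_df, data.frame(detectable = out))
}

inject_artifacts <- function(gs, pep, tables, truth_rows, clean_canon_set,
                             artifact_rates, n_clean, ds_ids) {
  add_rec <- function(ds, sequence, score, n_missed, prev_aa, next_aa,
                      class) {
    rec <- data.frame(sequence = sequence, dataset = ds,
                      engines = dataset_engines(ds), score = score,
                      enzyme = "trypsin", n_missed = n_missed,
                      prev_aa = prev_aa, next_aa = next_aa,
                      stringsAsFactors = FALSE)
    tables[[ds]] <<- rbind(tables[[ds]], rec)
    truth_rows[[length(truth_rows) + 1L]] <<-
      data.frame(dataset = ds, sequence = sequence, class = class,
                 gene_id = NA_character_, stringsAsFactors = FALSE)
  }
  n_of <- function(cls) {
    r <- artifact_rates[[cls]]
    if (r <= 0) 0L else max(1L, round(r * n_clean))
  }

  iso <- gs$isoforms[!gs$isoforms$read_through, , drop = FALSE]
  # unused fully tryptic peptides (never emitted cleanly anywhere)
  spare0 <- pep[pep$n_missed == 0L & !pep$canon %in% clean_canon_set, ,
                drop = FALSE]
  spare1 <- pep[pep$n_missed == 1L & !pep$canon %in% clean_canon_set, ,
                drop = FALSE]

  # non-tryptic substrings: both termini non-conforming
  n_nt <- n_of("non_tryptic")
  made <- 0L; tries <- 0L
  while (made < n_nt && tries < 50L * n_nt) {
    tries <- tries + 1L
    i <- sample(nrow(iso), 1L)
    prot <- iso$protein[i]
    len <- sample(8:14, 1L)
    if (nchar(prot) < len + 4L) next
    s <- sample(2:(nchar(prot) - len), 1L)
    sq <- substr(prot, s, s + len - 1L)
    prev <- substr(prot, s - 1L, s - 1L)
    nxt <- substr(prot, s + len, s + len)
    last <- substr(sq, len, len)
    if (prev %in% c("K", "R") || last %in% c("K", "R")) next
    if (canonical_il(sq) %in% clean_canon_set) next
    add_rec(sample(ds_ids, 1L), sq, dataset_score(ds_ids[1], TRUE), 0L,
            prev, nxt, "non_tryptic")
    made <- made + 1L
  }

  # sub-threshold scores in the score-filtered datasets
  score_ds <- intersect(c("ds1", "ds2", "ds3"), ds_ids)
  if (length(score_ds) && nrow(spare0)) {
    n_ss <- min(n_of("sub_score"), nrow(spare0))
    take <- sample(nrow(spare0), n_ss)
    for (j in take) {
      r <- spare0[j, ]
      add_rec(sample(score_ds, 1L), r$peptide, stats::runif(1, 20, 95), 0L,
              r$prev_aa, r$next_aa, "sub_score")
    }
    spare0 <- spare0[-take, , drop = FALSE]
  }

  # single-experiment peptides (pass all per-dataset rules, one dataset)
  lax_ds <- intersect(c("ds6", "ds7"), ds_ids)
  if (length(lax_ds) && nrow(spare0)) {
    n_se <- min(n_of("single_experiment"), nrow(spare0))
    take <- sample(nrow(spare0), n_se)
    for (j in take) {
      r <- spare0[j, ]
      add_rec(sample(lax_ds, 1L), r$peptide, dataset_score("ds6", TRUE), 0L,
              r$prev_aa, r$next_aa, "single_experiment")
    }
    spare0 <- spare0[-take, , drop = FALSE]
  }

  # unsupported missed cleavages: emitted in two datasets, sub-peptides
  # absent from both
  n_um <- n_of("unsupported_missed")
  made <- 0L
  clean_by_ds <- lapply(tables, function(t) canonical_il(t$sequence))
  if (nrow(spare1)) {
    for (j in sample(nrow(spare1))) {
      if (made >= n_um) break
      r <- spare1[j, ]
      subs <- digest_protein(r$peptide, "trypsin", 0L, 7L)
      if (!nrow(subs)) next  # unsupported by construction, still usable
      sub_canon <- canonical_il(subs$peptide)
      ok_ds <- ds_ids[vapply(ds_ids, function(ds)
        !any(sub_canon %in% clean_by_ds[[ds]]), logical(1))]
      if (length(ok_ds) < 2L) next
      for (ds in sample(ok_ds, 2L)) {
        add_rec(ds, r$peptide, dataset_score(ds, TRUE), 1L,
                r$prev_aa, r$next_aa, "unsupported_missed")
      }
      made <- made + 1L
    }
  }
  list(tables = tables, truth_rows = truth_rows)
}
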