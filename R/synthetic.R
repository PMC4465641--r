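# Synthetic annotation + proteomics generator with full ground truth.
#
# The generator builds multi-isoform gene models realizing all seven splice
# event kinds (plus read-through decoys, a UGT1A-style cluster of "genes"
# sharing common 3' exons, and pseudoautosomal decoys), places domain
# annotations with known impact verdicts, and simulates noisy
# multi-experiment peptide detections with labelled filter-target
# artifacts. Everything is deterministic under the seed.

revtrans_table <- function(t_free = FALSE) {
  gc <- Biostrings::GENETIC_CODE
  gc <- gc[gc != "*"]
  if (t_free) gc <- gc[!grepl("T", names(gc), fixed = TRUE)]
  split(names(gc), unname(gc))
}

sample_protein <- function(n, site_rate = 0.11, alphabet = AA20) {
  kr <- intersect(c("K", "R"), alphabet)
  rest <- setdiff(alphabet, c(kr, "P"))
  p_p <- if ("P" %in% alphabet) 0.02 else 0
  probs <- c(rep(site_rate / length(kr), length(kr)),
             rep((1 - site_rate - p_p) / length(rest), length(rest)),
             if (p_p > 0) p_p)
  letters_ <- c(kr, rest, if (p_p > 0) "P")
  paste(sample(letters_, n, replace = TRUE, prob = probs), collapse = "")
}

reverse_translate <- function(aa, codons) {
  paste(vapply(strsplit(aa, "")[[1]], function(a)
    sample(codons[[a]], 1L), character(1)), collapse = "")
}

mutate_protein <- function(aa, identity, alphabet = setdiff(AA20, c("K", "R", "P"))) {
  chars <- strsplit(aa, "")[[1]]
  n_mut <- round((1 - identity) * length(chars))
  if (n_mut > 0) {
    pos <- sample(length(chars), n_mut)
    for (p in pos) chars[p] <- sample(setdiff(alphabet, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Default pseudoautosomal decoy regions used by the generator
#' @return data.frame of 0-based half-open regions.
#' @export
synth_par_regions <- function() {
  data.frame(chrom = "chrX", start = 0L, end = 60000L,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic gene set with known splice events
#'
#' Builds `n_genes` protein-coding gene models on a synthetic chromosome.
#' A configurable fraction are single-isoform; the rest carry 1–3
#' alternative isoforms, each differing from the main isoform by exactly
#' one planted splice event whose kind follows `event_props`. Mutually
#' exclusive homologous exon pairs are created by duplicating-and-mutating
#' an exon at a recorded identity; frame-shifted overlapping-exon pairs
#' (two-protein events) use T-free codons so both frames are stop-free.
#' Optionally adds read-through decoy transcripts, pseudoautosomal decoy
#' genes, and one cluster of member "genes" sharing common 3' exons joined
#' to distinct homologous first exons. Domain annotations are placed so
#' that each event has a known domain-impact verdict following
#' `domain_props`.
#'
#' @param n_genes number of ordinary genes (decoys and cluster members are
#'   extra).
#' @param seed RNG seed; output is bit-identical for a fixed seed.
#' @param event_props named proportions over the seven event kinds
#'   (largest-remainder apportioned over alternative-isoform slots).
#' @param frac_single fraction of ordinary genes with a single isoform.
#' @param alt_dist distribution of the number of alternatives for
#'   multi-isoform genes (names "1","2","3").
#' @param include_cluster,cluster_size add a gene cluster with
#'   `cluster_size` members.
#' @param n_readthrough number of genes given a read-through decoy
#'   transcript.
#' @param n_par_decoys single-isoform decoy genes inside
#'   [synth_par_regions()].
#' @param hes_identity identity range for homologous exon pairs.
#' @param tryptic_site_rate combined K/R frequency in sampled proteins.
#' @param domain_props proportions of planted domain-impact verdicts over
#'   events (`broken`, `lost`, `swap`, `none`); events ineligible for a
#'   scenario fall back to `none`.
#' @return list with `gene_set`, `truth` (data.frames: `events`, `hes`,
#'   `domain_impacts`, plus `domains`, `clusters`, `par_genes`,
#'   `readthrough_isoforms`), and `genome` (named chromosome sequences).
#' @export
generate_gene_set <- function(n_genes = 200L, seed = 1L,
                              event_props = c(indel = 0.387, nagnag = 0.138,
                                              homologous_substitution = 0.213,
                                              cterm_substitution = 0.152,
                                              nterm_substitution = 0.085,
                                              internal_substitution = 0.007,
                                              two_proteins = 0.018),
                              frac_single = 0.2,
                              alt_dist = c(`1` = 0.75, `2` = 0.15, `3` = 0.10),
                              include_cluster = TRUE, cluster_size = 4L,
                              n_readthrough = 3L, n_par_decoys = 2L,
                              hes_identity = c(0.80, 0.95),
                              tryptic_site_rate = 0.11,
                              domain_props = c(broken = 0.07, lost = 0.07,
                                               swap = 0.02, none = 0.84)) {
  stopifnot(abs(sum(event_props) - 1) < 1e-6)
  with_seed(seed, generate_gene_set_impl(
    n_genes, event_props, frac_single, alt_dist, include_cluster,
    cluster_size, n_readthrough, n_par_decoys, hes_identity,
    tryptic_site_rate, domain_props))
}

generate_gene_set_impl <- function(n_genes, event_props, frac_single,
                                   alt_dist, include_cluster, cluster_size,
                                   n_readthrough, n_par_decoys, hes_identity,
                                   tryptic_site_rate, domain_props) {
  rt <- revtrans_table()
  rt_tfree <- revtrans_table(t_free = TRUE)
  tfree_alpha <- names(rt_tfree)

  n_multi <- round((1 - frac_single) * n_genes)
  n_alts <- c(sample(as.integer(names(alt_dist)), n_multi, replace = TRUE,
                     prob = alt_dist), rep(0L, n_genes - n_multi))
  # two_proteins is a whole-gene construction: allocate whole genes to it
  slots_total <- sum(pmax(n_alts, 0L))
  kind_counts <- apportion(slots_total, event_props)
  names(kind_counts) <- names(event_props)
  n_tp <- kind_counts[["two_proteins"]]
  tp_genes <- utils::head(which(n_alts == 1L), n_tp)
  kind_pool <- rep(names(kind_counts), kind_counts)
  kind_pool <- kind_pool[kind_pool != "two_proteins"]
  if (length(tp_genes) < n_tp)  # not enough 1-alt genes: reallocate
    kind_pool <- c(kind_pool, rep("indel", n_tp - length(tp_genes)))
  kind_pool <- sample(kind_pool)

  iso_rows <- list(); exon_rows <- list(); genome <- list()
  truth_events <- list(); truth_hes <- list(); domain_rows <- list()
  truth_impacts <- list(); rt_isoforms <- character()
  chrom_parts <- list(chr1 = list()); cursor <- 1000L
  pool_i <- 0L
  next_kind <- function() { pool_i <<- pool_i + 1L; kind_pool[pool_i] }

  rt_genes <- sample(setdiff(which(n_alts >= 1L), tp_genes),
                     min(n_readthrough, max(0L, n_multi - n_tp)))

  place_units <- function(units, strand, chrom = "chr1") {
    # units: list(id=, dna=, aa=, virtual=NULL|list(parent, trim_codons))
    real <- units[vapply(units, function(u) is.null(u$virtual), logical(1))]
    ord <- if (strand == "+") seq_along(real) else rev(seq_along(real))
    iv <- list()
    for (k in ord) {
      len <- nchar(real[[k]]$dna)
      iv[[real[[k]]$id]] <- c(cursor, cursor + len)
      seq_out <- if (strand == "+") real[[k]]$dna else
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(real[[k]]$dna)))
      chrom_parts[[chrom]][[length(chrom_parts[[chrom]]) + 1L]] <<-
        list(start = cursor, seq = seq_out)
      cursor <<- cursor + len + sample(80:160, 1L)
    }
    for (u in units) {
      if (!is.null(u$virtual)) {
        pa <- iv[[u$virtual$parent]]
        off <- 3L * u$virtual$trim_codons
        iv[[u$id]] <- if (strand == "+") c(pa[1] + off, pa[2])
                      else c(pa[1], pa[2] - off)
      }
    }
    iv
  }

  emit_isoform <- function(iso_id, gene_id, unit_ids, units, iv, strand,
                           read_through = FALSE, chrom = "chr1") {
    aa <- paste(vapply(unit_ids, function(id) units[[id]]$aa, character(1)),
                collapse = "")
    iso_rows[[length(iso_rows) + 1L]] <<- data.frame(
      isoform_id = iso_id, gene_id = gene_id, protein = aa,
      read_through = read_through, principal = FALSE,
      stringsAsFactors = FALSE)
    for (k in seq_along(unit_ids)) {
      u <- iv[[unit_ids[k]]]
      exon_rows[[length(exon_rows) + 1L]] <<- data.frame(
        isoform_id = iso_id, chrom = chrom, start = u[1], end = u[2],
        strand = strand, rank = k, stringsAsFactors = FALSE)
    }
    invisible(aa)
  }

  seg_bounds <- function(lens, k) {
    s <- if (k > 1L) sum(lens[seq_len(k - 1L)]) else 0L
    c(s + 1L, s + lens[k])
  }

  for (g in seq_len(n_genes)) {
    gene_id <- sprintf("GENE%04d", g)
    strand <- sample(c("+", "-"), 1L, prob = c(0.7, 0.3))

    if (g %in% tp_genes) {
      # frame-shifted overlapping single-exon pair: T-free codons
      L <- sample(30:60, 1L)
      aa_main <- sample_protein(L, tryptic_site_rate, tfree_alpha)
      dna <- reverse_translate(aa_main, rt_tfree)
      aa_alt <- translate_cds(substr(dna, 2L, 3L * L - 2L))
      units <- list(list(id = paste0(gene_id, "_e1"), dna = dna, aa = aa_main,
                         virtual = NULL),
                    list(id = paste0(gene_id, "_e1s"), aa = aa_alt,
                         virtual = list(parent = paste0(gene_id, "_e1"),
                                        trim_codons = 0L)))
      iv <- place_units(units, strand)
      # shift the alt interval by 1 nt in transcription direction, trim tail
      base <- iv[[paste0(gene_id, "_e1")]]
      iv[[paste0(gene_id, "_e1s")]] <- if (strand == "+")
        c(base[1] + 1L, base[2] - 2L) else c(base[1] + 2L, base[2] - 1L)
      unames <- stats::setNames(units, vapply(units, `[[`, "", "id"))
      main_id <- paste0(gene_id, ".1"); alt_id <- paste0(gene_id, ".2")
      emit_isoform(main_id, gene_id, paste0(gene_id, "_e1"), unames, iv, strand)
      emit_isoform(alt_id, gene_id, paste0(gene_id, "_e1s"), unames, iv, strand)
      truth_events[[length(truth_events) + 1L]] <- data.frame(
        gene_id = gene_id, main_isoform_id = main_id, alt_isoform_id = alt_id,
        kind = "two_proteins", main_start = 1L, main_end = L,
        alt_start = 1L, alt_end = nchar(aa_alt), alt_junction = NA_integer_,
        stringsAsFactors = FALSE)
      next
    }

    k_alts <- n_alts[g]
    n_ex <- max(4L, k_alts + 2L) + sample(0:2, 1L)
    kinds <- if (k_alts > 0L) vapply(seq_len(k_alts), function(i) next_kind(),
                                     character(1)) else character()
    # one distinct target exon per alternative
    internal <- 2:(n_ex - 1L)
    targets <- integer(k_alts)
    pool_internal <- sample(internal)
    pi <- 0L
    for (i in seq_len(k_alts)) {
      targets[i] <- switch(kinds[i],
                           nterm_substitution = 1L,
                           cterm_substitution = n_ex,
                           { pi <- pi + 1L; pool_internal[pi] })
    }
    # exon lengths in codons, honouring event constraints
    lens <- sample(8:30, n_ex, replace = TRUE)
    hes_exempt <- logical(k_alts)
    for (i in seq_len(k_alts)) {
      t <- targets[i]
      if (kinds[i] == "homologous_substitution") {
        hes_exempt[i] <- stats::runif(1) < 0.3
        lens[t] <- sample(if (hes_exempt[i]) 20:35 else 15:35, 1L)
      }
      if (kinds[i] == "indel") lens[t] <- sample(6:30, 1L)
      if (kinds[i] == "nagnag") lens[t] <- sample(7:30, 1L)
    }

    units <- list()
    for (k in seq_len(n_ex)) {
      aa <- sample_protein(lens[k], tryptic_site_rate)
      units[[paste0(gene_id, "_e", k)]] <-
        list(id = paste0(gene_id, "_e", k), aa = aa,
             dna = reverse_translate(aa, rt), virtual = NULL)
    }
    main_units <- paste0(gene_id, "_e", seq_len(n_ex))

    alt_unit_lists <- list(); ev_meta <- list()
    for (i in seq_len(k_alts)) {
      t <- targets[i]; kind <- kinds[i]
      vid <- paste0(gene_id, "_v", i)
      alt_units <- main_units
      S <- seg_bounds(lens, t)
      meta <- list(kind = kind, main_start = S[1], main_end = S[2],
                   alt_start = NA_integer_, alt_end = NA_integer_,
                   alt_junction = NA_integer_)
      if (kind == "indel") {
        alt_units <- main_units[-t]
        meta$alt_junction <- S[1] - 1L
      } else if (kind == "nagnag") {
        d <- sample(1:4, 1L)
        parent <- paste0(gene_id, "_e", t)
        units[[vid]] <- list(id = vid,
                             aa = substr(units[[parent]]$aa, d + 1L, lens[t]),
                             dna = NULL,
                             virtual = list(parent = parent, trim_codons = d))
        alt_units[t] <- vid
        meta$main_end <- S[1] + d - 1L
        meta$alt_junction <- S[1] - 1L
      } else {
        # substitution kinds: replacement exon after the target exon
        if (kind == "homologous_substitution") {
          q <- stats::runif(1, hes_identity[1], hes_identity[2])
          base <- units[[paste0(gene_id, "_e", t)]]$aa
          if (hes_exempt[i]) base <- substr(base, 1L, nchar(base) - 6L)
          aa_new <- mutate_protein(base, q)
          meta$hes_identity <- q
        } else {
          L_new <- sample(5:max(6L, lens[t] - 1L), 1L)
          aa_new <- sample_protein(L_new, tryptic_site_rate)
        }
        units[[vid]] <- list(id = vid, aa = aa_new,
                             dna = reverse_translate(aa_new, rt),
                             virtual = NULL)
        alt_units[t] <- vid
        meta$alt_start <- S[1]
        meta$alt_end <- S[1] + nchar(aa_new) - 1L
      }
      alt_unit_lists[[i]] <- alt_units
      ev_meta[[i]] <- meta
    }

    # genomic layout: main exon k, then its variant exons, in order
    layout <- list()
    for (k in seq_len(n_ex)) {
      layout[[length(layout) + 1L]] <- units[[paste0(gene_id, "_e", k)]]
      for (i in seq_len(k_alts)) {
        if (k_alts > 0L && targets[i] == k) {
          vid <- paste0(gene_id, "_v", i)
          if (!is.null(units[[vid]]) && is.null(units[[vid]]$virtual))
            layout[[length(layout) + 1L]] <- units[[vid]]
        }
      }
    }
    # read-through extra exon
    is_rt <- g %in% rt_genes
    if (is_rt) {
      aa_rt <- sample_protein(12L, tryptic_site_rate)
      units[[paste0(gene_id, "_rt")]] <- list(id = paste0(gene_id, "_rt"),
                                              aa = aa_rt,
                                              dna = reverse_translate(aa_rt, rt),
                                              virtual = NULL)
      layout[[length(layout) + 1L]] <- units[[paste0(gene_id, "_rt")]]
    }
    vir <- units[vapply(units, function(u) !is.null(u$virtual), logical(1))]
    for (v in vir) layout[[length(layout) + 1L]] <- v
    iv <- place_units(layout, strand)

    main_id <- paste0(gene_id, ".1")
    emit_isoform(main_id, gene_id, main_units, units, iv, strand)
    for (i in seq_len(k_alts)) {
      alt_id <- paste0(gene_id, ".", i + 1L)
      emit_isoform(alt_id, gene_id, alt_unit_lists[[i]], units, iv, strand)
      m <- ev_meta[[i]]
      truth_events[[length(truth_events) + 1L]] <- data.frame(
        gene_id = gene_id, main_isoform_id = main_id, alt_isoform_id = alt_id,
        kind = m$kind, main_start = m$main_start, main_end = m$main_end,
        alt_start = m$alt_start, alt_end = m$alt_end,
        alt_junction = m$alt_junction, stringsAsFactors = FALSE)
      if (m$kind == "homologous_substitution") {
        tu <- iv[[paste0(gene_id, "_e", targets[i])]]
        vu <- iv[[paste0(gene_id, "_v", i)]]
        truth_hes[[length(truth_hes) + 1L]] <- data.frame(
          gene_id = gene_id,
          exon_a = paste0("chr1:", tu[1], "-", tu[2], ":", strand),
          exon_b = paste0("chr1:", vu[1], "-", vu[2], ":", strand),
          identity = m$hes_identity, stringsAsFactors = FALSE)
      }
    }
    if (is_rt) {
      rt_id <- paste0(gene_id, ".rt")
      emit_isoform(rt_id, gene_id, c(main_units, paste0(gene_id, "_rt")),
                   units, iv, strand, read_through = TRUE)
      rt_isoforms <- c(rt_isoforms, rt_id)
    }
  }

  # UGT1A-style cluster: distinct homologous first exons + common 3' exons
  clusters <- data.frame(cluster_name = character(),
                         member_gene_ids = character(),
                         stringsAsFactors = FALSE)
  if (include_cluster && cluster_size >= 2L) {
    strand <- "+"
    L1 <- 25L
    first_aa <- sample_protein(L1 + 4L, tryptic_site_rate)  # longest member
    common_aa <- lapply(1:3, function(k) sample_protein(sample(12:25, 1L),
                                                        tryptic_site_rate))
    units <- list()
    member_ids <- sprintf("CLUM%02d", seq_len(cluster_size))
    for (i in seq_len(cluster_size)) {
      aa <- if (i == 1L) first_aa
            else mutate_protein(substr(first_aa, 1L, L1),
                                stats::runif(1, 0.82, 0.92))
      id <- paste0("CLU_f", i)
      units[[id]] <- list(id = id, aa = aa, dna = reverse_translate(aa, rt),
                          virtual = NULL)
    }
    for (k in 1:3) {
      id <- paste0("CLU_c", k)
      units[[id]] <- list(id = id, aa = common_aa[[k]],
                          dna = reverse_translate(common_aa[[k]], rt),
                          virtual = NULL)
    }
    iv <- place_units(units, strand)
    for (i in seq_len(cluster_size)) {
      iso <- paste0(member_ids[i], ".1")
      emit_isoform(iso, member_ids[i],
                   c(paste0("CLU_f", i), paste0("CLU_c", 1:3)), units, iv,
                   strand)
      if (i > 1L) {
        fu1 <- iv[["CLU_f1"]]; fui <- iv[[paste0("CLU_f", i)]]
        Lm <- nchar(units[["CLU_f1"]]$aa); La <- nchar(units[[paste0("CLU_f", i)]]$aa)
        truth_events[[length(truth_events) + 1L]] <- data.frame(
          gene_id = "UGTX_cluster", main_isoform_id = paste0(member_ids[1], ".1"),
          alt_isoform_id = iso, kind = "homologous_substitution",
          main_start = 1L, main_end = Lm, alt_start = 1L, alt_end = La,
          alt_junction = NA_integer_, stringsAsFactors = FALSE)
        truth_hes[[length(truth_hes) + 1L]] <- data.frame(
          gene_id = "UGTX_cluster",
          exon_a = paste0("chr1:", fu1[1], "-", fu1[2], ":", strand),
          exon_b = paste0("chr1:", fui[1], "-", fui[2], ":", strand),
          identity = NA_real_, stringsAsFactors = FALSE)
      }
    }
    clusters <- data.frame(cluster_name = "UGTX_cluster",
                           member_gene_ids = paste(member_ids, collapse = ";"),
                           stringsAsFactors = FALSE)
  }

  # pseudoautosomal decoy genes on chrX
  par_genes <- character()
  if (n_par_decoys > 0L) {
    chrom_parts$chrX <- list()
    par_cursor <- 5000L
    for (i in seq_len(n_par_decoys)) {
      gid <- sprintf("PARG%02d", i)
      aa <- sample_protein(60L, tryptic_site_rate)
      dna <- reverse_translate(aa, rt)
      chrom_parts$chrX[[length(chrom_parts$chrX) + 1L]] <-
        list(start = par_cursor, seq = dna)
      iso_rows[[length(iso_rows) + 1L]] <- data.frame(
        isoform_id = paste0(gid, ".1"), gene_id = gid, protein = aa,
        read_through = FALSE, principal = FALSE, stringsAsFactors = FALSE)
      exon_rows[[length(exon_rows) + 1L]] <- data.frame(
        isoform_id = paste0(gid, ".1"), chrom = "chrX", start = par_cursor,
        end = par_cursor + nchar(dna), strand = "+", rank = 1L,
        stringsAsFactors = FALSE)
      par_cursor <- par_cursor + nchar(dna) + 500L
      par_genes <- c(par_genes, gid)
    }
  }

  gs <- gene_set(do.call(rbind, iso_rows), do.call(rbind, exon_rows))
  events_df <- do.call(rbind, truth_events)
  if (is.null(events_df))
    events_df <- data.frame(gene_id = character(),
                            main_isoform_id = character(),
                            alt_isoform_id = character(), kind = character(),
                            main_start = integer(), main_end = integer(),
                            alt_start = integer(), alt_end = integer(),
                            alt_junction = integer(), stringsAsFactors = FALSE)
  rownames(events_df) <- NULL
  hes_df <- if (length(truth_hes)) do.call(rbind, truth_hes) else
    data.frame(gene_id = character(), exon_a = character(),
               exon_b = character(), identity = numeric(),
               stringsAsFactors = FALSE)

  dom <- plant_domains(gs, events_df, domain_props)

  genome <- lapply(chrom_parts, assemble_chromosome)

  list(gene_set = gs,
       truth = list(events = events_df, hes = hes_df,
                    domains = dom$table, domain_impacts = dom$impacts,
                    clusters = clusters, par_genes = par_genes,
                    readthrough_isoforms = rt_isoforms),
       genome = genome)
}

assemble_chromosome <- function(parts) {
  if (!length(parts)) return("")
  total <- max(vapply(parts, function(p) p$start + nchar(p$seq), numeric(1)))
  chars <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  for (p in parts) {
    idx <- seq.int(p$start + 1L, p$start + nchar(p$seq))
    chars[idx] <- strsplit(p$seq, "")[[1]]
  }
  paste(chars, collapse = "")
}

# Place domain annotations realizing a target verdict mix. Events
# ineligible for their assigned scenario fall back to "none". Domains are
# only planted for genes with a single alternative isoform: planting on a
# shared main isoform would couple the verdicts of that gene's events.
plant_domains <- function(gs, events_df, domain_props) {
  n <- nrow(events_df)
  single_alt <- names(which(table(events_df$gene_id) == 1L))
  scen <- rep(names(domain_props), apportion(n, domain_props))
  scen <- sample(scen)
  rows <- list(); impacts <- character(n)
  add <- function(iso, acc, s, e)
    rows[[length(rows) + 1L]] <<- data.frame(isoform_id = iso, domain_acc = acc,
                                             start = s, end = e,
                                             stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ev <- events_df[i, ]
    s <- ev$main_start; e <- ev$main_end
    lm <- e - s + 1L
    la <- if (is.na(ev$alt_start)) 0L else ev$alt_end - ev$alt_start + 1L
    sc <- scen[i]
    if (!ev$gene_id %in% single_alt) { impacts[i] <- "none"; next }
    if (ev$kind == "homologous_substitution") {
      # domain spanning the homologous exon on both sides: unbroken by rule
      add(ev$main_isoform_id, "PFhes", s, e)
      add(ev$alt_isoform_id, "PFhes", ev$alt_start, ev$alt_end)
      impacts[i] <- "none"
      next
    }
    if (ev$kind == "two_proteins") { impacts[i] <- "none"; next }
    ok_broken <- ev$kind %in% c("indel") && lm >= 5L && s >= 9L
    ok_lost <- ev$kind %in% c("indel") && lm >= 7L && s >= 10L
    ok_swap <- ev$kind %in% c("cterm_substitution", "nterm_substitution",
                              "internal_substitution") && lm >= 4L && la >= 4L
    if (sc == "broken" && ok_broken) {
      add(ev$main_isoform_id, "PFbrk", s - 8L, s + 4L)
      add(ev$alt_isoform_id, "PFbrk", s - 8L, s - 1L)
      impacts[i] <- "broken"
    } else if (sc == "lost" && ok_lost) {
      add(ev$main_isoform_id, "PFlost", s + 1L, e - 1L)
      add(ev$main_isoform_id, "PFkeep", 2L, min(8L, s - 2L))
      add(ev$alt_isoform_id, "PFkeep", 2L, min(8L, s - 2L))
      impacts[i] <- "lost"
    } else if (sc == "swap" && ok_swap) {
      add(ev$main_isoform_id, "PFswapA", s, s + lm - 1L)
      add(ev$alt_isoform_id, "PFswapB", ev$alt_start, ev$alt_start + la - 1L)
      impacts[i] <- "swap"
    } else {
      if (s > 12L) {  # intact domain in the shared prefix of both isoforms
        add(ev$main_isoform_id, "PFnone", 2L, 10L)
        add(ev$alt_isoform_id, "PFnone", 2L, 10L)
      }
      impacts[i] <- "none"
    }
  }
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(isoform_id = character(), domain_acc = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  impacts_df <- cbind(events_df[, c("gene_id", "main_isoform_id",
                                    "alt_isoform_id", "kind")],
                      data.frame(verdict = impacts, stringsAsFactors = FALSE))
  list(table = table, impacts = impacts_df)
}
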