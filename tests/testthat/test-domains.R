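mk_ev <- function(kind, ms, me, as_ = NA, ae = NA, main_len = 200L,
                  alt_len = NULL) {
  lm <- me - ms + 1L
  la <- if (is.na(as_)) 0L else ae - as_ + 1L
  structure(list(gene_id = "G", main_isoform_id = "a", alt_isoform_id = "b",
                 main_segment = c(ms, me),
                 alt_segment = if (is.na(as_)) NULL else c(as_, ae),
                 main_len = main_len,
                 alt_len = alt_len %||% (main_len - lm + la),
                 main_seq = strrep("A", lm), alt_seq = strrep("A", la),
                 main_flank = c(ms - 1L, me + 1L),
                 alt_flank = if (is.na(as_)) c(ms - 1L, ms) else
                   c(as_ - 1L, ae + 1L),
                 no_match = FALSE, kind = kind), class = "splice_event")
}
`%||%` <- function(a, b) if (is.null(a)) b else a
dom <- function(acc, s, e) data.frame(domain_acc = acc, start = s, end = e,
                                      stringsAsFactors = FALSE)

test_that("the five-residue rule separates broken from untouched domains", {
  # 10-residue deletion inside a domain: broken
  ev <- mk_ev("indel", 50L, 59L)
  r <- event_domain_effect(ev, dom("PF1", 40L, 80L), dom("PF1", 40L, 70L))
  expect_identical(r$verdict, "broken")
  # 4-residue loss: not broken
  ev4 <- mk_ev("nagnag", 50L, 53L)
  r4 <- event_domain_effect(ev4, dom("PF1", 40L, 80L), dom("PF1", 40L, 76L))
  expect_identical(r4$verdict, "none")
  # exactly 5: broken (boundary)
  ev5 <- mk_ev("indel", 50L, 54L)
  r5 <- event_domain_effect(ev5, dom("PF1", 40L, 80L), dom("PF1", 40L, 75L))
  expect_identical(r5$verdict, "broken")
})

test_that("whole-domain loss and domain swaps are recognised", {
  # domain wholly inside the deleted segment, another domain intact
  ev <- mk_ev("indel", 50L, 90L)
  r <- event_domain_effect(ev,
                           rbind(dom("PF1", 55L, 85L), dom("PF2", 5L, 20L)),
                           dom("PF2", 5L, 20L))
  expect_identical(r$verdict, "lost")
  # NEBL-like: N-terminal repeats replaced by a different domain
  ev <- mk_ev("nterm_substitution", 1L, 120L, 1L, 30L)
  r <- event_domain_effect(ev, dom("PFnebulin", 10L, 110L),
                           dom("PFLIM", 2L, 28L))
  expect_identical(r$verdict, "swap")
})

test_that("homologous substitutions coinciding with domains stay unbroken", {
  ev <- mk_ev("homologous_substitution", 50L, 90L, 50L, 84L)
  main_d <- dom("PF1", 50L, 90L)
  alt_d <- dom("PF1", 50L, 84L)   # 6 residues shorter
  expect_identical(event_domain_effect(ev, main_d, alt_d)$verdict, "none")
  # the per-domain override lifts the exemption (ATP2B1/ATP2B4-style)
  expect_identical(
    event_domain_effect(ev, main_d, alt_d, break_overrides = "PF1")$verdict,
    "broken")
})

test_that("tallies are complete, order-invariant and degrade to none", {
  syn <- small_synth()
  fit <- small_scan()
  t1 <- tally_domain_effects(fit$events, syn$truth$domains)
  expect_identical(sum(t1$counts), length(fit$events))
  expect_equal(sum(t1$percentages), 100)
  # shuffled domain table gives identical verdicts
  set.seed(1)
  shuf <- syn$truth$domains[sample(nrow(syn$truth$domains)), ]
  t2 <- tally_domain_effects(fit$events, shuf)
  expect_identical(t2$counts, t1$counts)
  # no domain annotations at all: everything none
  empty <- syn$truth$domains[0, ]
  t3 <- tally_domain_effects(fit$events, empty)
  expect_identical(unname(t3$counts["none"]), length(fit$events))
})

test_that("planted domain-impact verdicts are recovered exactly", {
  syn <- small_synth()
  gs <- merge_gene_clusters(syn$gene_set, syn$truth$clusters)
  gs <- mark_principal(gs)
  truth <- syn$truth$domain_impacts
  for (i in seq_len(nrow(truth))) {
    evs <- extract_events(gs, truth$main_isoform_id[i],
                          truth$alt_isoform_id[i])
    if (length(evs) != 1L) next
    ev <- evs[[1]]
    ev$kind <- truth$kind[i]
    d <- syn$truth$domains
    r <- event_domain_effect(
      ev, d[d$isoform_id == truth$main_isoform_id[i], ],
      d[d$isoform_id == truth$alt_isoform_id[i], ])
    expect_identical(r$verdict, truth$verdict[i])
  }
})

test_that("a planted 30/30/10/30 scenario mix is tallied exactly", {
  syn <- generate_gene_set(60L, seed = 31L,
                           event_props = c(indel = 0.6, nagnag = 0,
                                           homologous_substitution = 0,
                                           cterm_substitution = 0.2,
                                           nterm_substitution = 0.1,
                                           internal_substitution = 0.1,
                                           two_proteins = 0),
                           domain_props = c(broken = 0.3, lost = 0.3,
                                            swap = 0.1, none = 0.3),
                           include_cluster = FALSE, n_readthrough = 0L,
                           n_par_decoys = 0L)
  gs <- mark_principal(syn$gene_set)
  truth <- syn$truth$domain_impacts
  events <- list()
  for (i in seq_len(nrow(truth))) {
    evs <- extract_events(gs, truth$main_isoform_id[i],
                          truth$alt_isoform_id[i])
    evs[[1]]$kind <- truth$kind[i]
    events[[i]] <- evs[[1]]
  }
  tl <- tally_domain_effects(events, syn$truth$domains)
  want <- table(factor(truth$verdict,
                       c("broken", "lost", "swap", "none")))
  expect_identical(unname(tl$counts), as.integer(want))
  expect_gt(tl$counts[["broken"]], 0L)
  expect_gt(tl$counts[["lost"]], 0L)
  expect_gt(tl$counts[["swap"]], 0L)
})
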