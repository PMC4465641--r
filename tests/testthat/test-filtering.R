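mk_rec <- function(sequence, dataset = "ds1", engines = "andromeda",
                   score = 150, enzyme = "trypsin", n_missed = 0L,
                   prev_aa = "-", next_aa = "-") {
  data.frame(sequence = sequence, dataset = dataset, engines = engines,
             score = score, enzyme = enzyme, n_missed = n_missed,
             prev_aa = prev_aa, next_aa = next_aa, stringsAsFactors = FALSE)
}

test_that("score threshold is inclusive at the boundary", {
  cfg <- dataset_filter_config("ds1", min_score = 100)
  recs <- rbind(mk_rec("AAAAAAR", score = 99, prev_aa = "K"),
                mk_rec("CCCCCCK", score = 100, prev_aa = "K"),
                mk_rec("DDDDDDR", score = 150, prev_aa = "R"))
  out <- apply_dataset_filters(recs, cfg)
  expect_setequal(out$peptides$sequence, c("CCCCCCK", "DDDDDDR"))
  expect_identical(unname(out$audit["below_score"]), 1L)
  expect_error(
    apply_dataset_filters(mk_rec("AAAAAAR", score = NA, prev_aa = "K"), cfg),
    "ds1")
})

test_that("engine-agreement and enzyme rules drop records", {
  cfg <- dataset_filter_config("ds4", min_engines = 2L,
                               allowed_enzymes = c("trypsin", "lysc"))
  recs <- rbind(mk_rec("AAAAAAR", engines = "mascot", prev_aa = "K"),
                mk_rec("CCCCCCK", engines = "mascot;sequest", prev_aa = "K"),
                mk_rec("DDDDDDR", engines = "mascot;sequest",
                       enzyme = "gluc", prev_aa = "E"))
  out <- apply_dataset_filters(recs, cfg)
  expect_identical(out$peptides$sequence, "CCCCCCK")
  expect_identical(unname(out$audit[c("too_few_engines",
                                      "disallowed_enzyme")]), c(1L, 1L))
})

test_that("specificity filtering removes non- and semi-specific peptides", {
  cfg <- dataset_filter_config("ds1")
  recs <- rbind(
    mk_rec("AAAAAAR", prev_aa = "K", next_aa = "G"),   # fully tryptic
    mk_rec("AAAAAAG", prev_aa = "K", next_aa = "G"),   # semi (bad C-term)
    mk_rec("AAAAAAR", prev_aa = "G", next_aa = "G"),   # semi (bad N-term)
    mk_rec("AAAAAAG", prev_aa = "G", next_aa = "G"),   # non-specific
    mk_rec("AAAAAAG", prev_aa = "-", next_aa = "-"),   # whole protein
    mk_rec("PAAAAAR", prev_aa = "K", next_aa = "G"))   # K|P not a cut site
  out <- apply_dataset_filters(recs, cfg)
  expect_identical(nrow(out$peptides), 2L)
  expect_identical(unname(out$audit["non_specific"]), 4L)
  # audit counts account for all removals
  expect_identical(nrow(recs) - nrow(out$peptides), sum(out$audit))
})

test_that("empty input yields empty output and zeroed audit", {
  out <- apply_dataset_filters(mk_rec("AAAAAAR")[0, ],
                               dataset_filter_config("ds1", min_score = 10))
  expect_identical(nrow(out$peptides), 0L)
  expect_true(all(out$audit == 0L))
})

test_that("missed cleavages need a fully cleaved sub-peptide in the set", {
  recs <- rbind(
    mk_rec("AAAAAAKGGGGGGR", n_missed = 1L, prev_aa = "K"),
    mk_rec("GGGGGGR", prev_aa = "K"),
    mk_rec("CCCCCCKDDDDDDR", n_missed = 1L, prev_aa = "K"))  # unsupported
  out <- enforce_missed_cleavage_support(recs)
  expect_setequal(out$peptides$sequence, c("AAAAAAKGGGGGGR", "GGGGGGR"))
  expect_identical(unname(out$audit["unsupported_missed"]), 1L)
  # support is I/L-insensitive
  recs2 <- rbind(mk_rec("AAAILAAKGGILGGR", n_missed = 1L, prev_aa = "K"),
                 mk_rec("GGLLGGR", prev_aa = "K"))
  expect_identical(nrow(enforce_missed_cleavage_support(recs2)$peptides), 2L)
  # a 0-missed-only set passes through unchanged
  recs3 <- mk_rec(c("AAAAAAR", "CCCCCCK"), prev_aa = "K")
  expect_identical(enforce_missed_cleavage_support(recs3)$peptides$sequence,
                   recs3$sequence)
})

test_that("cross-experiment filter keeps peptides seen in >= 2 datasets", {
  sets <- list(
    ds1 = mk_rec(c("AAAIAAR", "CCCCCCK"), dataset = "ds1", prev_aa = "K"),
    ds2 = mk_rec(c("AAAIAAR", "DDDDDDR"), dataset = "ds2", prev_aa = "K"),
    ds3 = mk_rec(c("AAALAAR", "EEEEEEK", "DDDDDDR"), dataset = "ds3",
                 prev_aa = "K"))
  out <- cross_experiment_filter(sets, 2L)
  # AAAIAAR in ds1+ds2 and in ds3 as its I/L twin; DDDDDDR in ds2+ds3
  expect_setequal(out$canon_seq, c("AAALAAR", "DDDDDDR"))
  expect_identical(out$n_datasets[out$canon_seq == "AAALAAR"], 3L)
  # brute-force multiset check on provenance
  all <- do.call(rbind, sets)
  tab <- table(unique(data.frame(canonical_il(all$sequence),
                                 all$dataset))[, 1])
  expect_setequal(out$canon_seq, names(tab)[tab >= 2])
  expect_error(cross_experiment_filter(sets, 4L), "exceeds")
})

test_that("filters are contractive and stable under re-application", {
  det <- small_detect()
  for (ds in names(det$tables)[1:3]) {
    cfg <- det$configs[[ds]]
    once <- apply_dataset_filters(det$tables[[ds]], cfg)
    twice <- apply_dataset_filters(once$peptides, cfg)
    expect_true(nrow(once$peptides) <= nrow(det$tables[[ds]]))
    expect_identical(twice$peptides, once$peptides)
    m1 <- enforce_missed_cleavage_support(once)
    m2 <- enforce_missed_cleavage_support(m1$peptides)
    expect_identical(m2$peptides, m1$peptides)
  }
})

test_that("injected artifacts are removed and clean replicated peptides kept", {
  det <- small_detect()
  fit <- small_scan()
  surv <- fit$peptides$canon_seq
  art <- det$truth[det$truth$class != "clean", ]
  expect_gt(nrow(art), 0)
  expect_identical(sum(canonical_il(art$sequence) %in% surv), 0L)
  expect_setequal(surv, det$expected$final_canon)
})
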