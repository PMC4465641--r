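# Shared fixtures (memoized per session) and independent oracles.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small synthetic annotation + detections for module tests
small_synth <- function() memo("small_synth", generate_gene_set(60L, seed = 7L))
small_detect <- function() memo("small_detect",
                                simulate_detections(small_synth(), seed = 11L))
small_scan <- function() memo("small_scan", {
  syn <- small_synth(); det <- small_detect()
  splice_scan(syn$gene_set, det$tables, dataset_configs = det$configs,
              clusters = syn$truth$clusters,
              domain_annotations = syn$truth$domains)
})

# the acceptance-scale fixture (200 genes, fixed seed)
big_synth <- function() memo("big_synth", generate_gene_set(200L, seed = 101L))
big_detect <- function() memo("big_detect",
                              simulate_detections(big_synth(), seed = 202L))
big_scan <- function() memo("big_scan", {
  syn <- big_synth(); det <- big_detect()
  splice_scan(syn$gene_set, det$tables, dataset_configs = det$configs,
              clusters = syn$truth$clusters,
              domain_annotations = syn$truth$domains)
})

# --- independent oracles -------------------------------------------------

# brute-force digestion: enumerate cleavage boundaries directly
oracle_digest <- function(protein, enzyme = "trypsin", max_missed = 0L,
                          min_len = 7L, proline_rule = TRUE) {
  res <- strsplit(protein, "")[[1]]
  n <- length(res)
  rules <- switch(enzyme, trypsin = c("K", "R"), lysc = "K",
                  chymotrypsin = c("F", "W", "Y"), gluc = c("E", "D"))
  cut_after <- rep(FALSE, n)
  for (i in seq_len(n - 1))
    cut_after[i] <- res[i] %in% rules && !(proline_rule && res[i + 1] == "P")
  bounds <- c(0L, which(cut_after), n)
  out <- list()
  for (bi in seq_len(length(bounds) - 1)) {
    for (bj in (bi + 1):length(bounds)) {
      miss <- bj - bi - 1L
      if (miss > max_missed) break
      s <- bounds[bi] + 1L; e <- bounds[bj]
      if (e - s + 1L >= min_len)
        out[[length(out) + 1L]] <- data.frame(
          peptide = paste(res[s:e], collapse = ""), start = s,
          n_missed = miss, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(peptide = character(),
                                      start = integer(),
                                      n_missed = integer()))
  do.call(rbind, out)
}

# brute-force two-sided Fisher p: enumerate all tables with fixed margins
# using explicit factorial arithmetic
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  lo <- max(0L, c1 - r2); hi <- min(c1, r1)
  logp <- function(x) {
    lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(n - c1) -
      lfactorial(n) - lfactorial(x) - lfactorial(r1 - x) -
      lfactorial(c1 - x) - lfactorial(r2 - c1 + x)
  }
  ps <- exp(vapply(lo:hi, logp, numeric(1)))
  p_obs <- exp(logp(a))
  min(1, sum(ps[ps <= p_obs * (1 + 1e-7)]))
}

random_protein <- function(n, include_p = TRUE) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          if (include_p) "P", "Q", "R", "S", "T", "V", "W", "Y")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# toy single-gene set: main isoform with an in-frame insertion in the alt
# (see nullsim enumeration test); returns the gene_set
toy_insertion_gene <- function() {
  pa <- "AAAAAARCCCCGGGGKDDDDDDRFFFFFFK"
  pb <- "AAAAAARCCCCWWWGGGGKDDDDDDRFFFFFFK"
  iso <- data.frame(isoform_id = c("TOY.1", "TOY.2"), gene_id = "TOY",
                    protein = c(pa, pb), read_through = FALSE,
                    principal = c(TRUE, FALSE), stringsAsFactors = FALSE)
  exons <- rbind(
    data.frame(isoform_id = "TOY.1", chrom = "chrT", start = 0L,
               end = 3L * nchar(pa), strand = "+", rank = 1L),
    data.frame(isoform_id = "TOY.2",
               chrom = "chrT",
               start = c(0L, 500L, 33L),
               end = c(33L, 509L, 3L * nchar(pa)),
               strand = "+", rank = 1:3))
  gene_set(iso, exons)
}
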