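#' Per-dataset peptide filter configuration
#'
#' Captures the quality rules applied to one experiment's peptide table:
#' a minimum search-engine score (engine-specific scale, never compared
#' across datasets), a minimum number of agreeing search engines, the set
#' of digestion enzymes accepted, and whether full enzyme specificity is
#' required at both termini.
#'
#' @param dataset_id dataset identifier the config applies to.
#' @param min_score minimum score, or `NULL` for no score filter.
#' @param min_engines minimum number of search engines per identification.
#' @param allowed_enzymes enzymes accepted for this dataset, or `NULL`
#'   for any.
#' @param require_fully_specific drop non- and semi-specific peptides.
#' @param proline_rule proline suppression used when judging specificity.
#' @return A `dataset_filter_config` list.
#' @export
dataset_filter_config <- function(dataset_id, min_score = NULL,
                                  min_engines = 1L, allowed_enzymes = NULL,
                                  require_fully_specific = TRUE,
                                  proline_rule = TRUE) {
  stopifnot(min_engines >= 1L)
  structure(list(dataset_id = dataset_id, min_score = min_score,
                 min_engines = as.integer(min_engines),
                 allowed_enzymes = allowed_enzymes,
                 require_fully_specific = require_fully_specific,
                 proline_rule = proline_rule),
            class = "dataset_filter_config")
}

# Terminus conformity under the enzyme rule; protein termini ("-") conform.
specificity_flags <- function(df, proline_rule = TRUE) {
  first <- substr(df$sequence, 1L, 1L)
  last <- substr(df$sequence, nchar(df$sequence), nchar(df$sequence))
  n_ok <- logical(nrow(df))
  c_ok <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    rules <- enzyme_residues(df$enzyme[i])
    p <- df$prev_aa[i]
    n_ok[i] <- p %in% "-" ||
      (p %in% rules && !(proline_rule && first[i] == "P"))
    nx <- df$next_aa[i]
    c_ok[i] <- nx %in% "-" ||
      (last[i] %in% rules && !(proline_rule && nx == "P"))
  }
  cbind(n_ok = n_ok, c_ok = c_ok)
}

#' Apply per-dataset quality filters to peptide records
#'
#' Removes, in order: records whose enzyme is not allowed for the dataset;
#' records that are not fully enzyme-specific at both termini (semi- and
#' non-specific peptides, judged from the flanking-residue context with
#' protein termini counting as conforming); records below the dataset's
#' score threshold; and records identified by fewer than the required
#' number of search engines. An audit table counts removals per rule.
#'
#' @param peptides data.frame of peptide records (see
#'   [read_peptide_table()] for the column contract).
#' @param config a [dataset_filter_config()].
#' @return A `filtered_peptides` list with elements `peptides` (the
#'   surviving records) and `audit` (named integer vector of removals).
#' @export
apply_dataset_filters <- function(peptides, config) {
  stopifnot(inherits(config, "dataset_filter_config"))
  audit <- c(disallowed_enzyme = 0L, non_specific = 0L,
             below_score = 0L, too_few_engines = 0L)
  df <- peptides
  if (nrow(df)) {
    if (!is.null(config$allowed_enzymes)) {
      drop <- !df$enzyme %in% config$allowed_enzymes
      audit["disallowed_enzyme"] <- sum(drop)
      df <- df[!drop, , drop = FALSE]
    }
    if (config$require_fully_specific && nrow(df)) {
      sp <- specificity_flags(df, config$proline_rule)
      drop <- !(sp[, "n_ok"] & sp[, "c_ok"])
      audit["non_specific"] <- sum(drop)
      df <- df[!drop, , drop = FALSE]
    }
    if (!is.null(config$min_score) && nrow(df)) {
      if (anyNA(df$score))
        stop("records missing a score in dataset ", config$dataset_id,
             " but a score threshold is set", call. = FALSE)
      drop <- df$score < config$min_score
      audit["below_score"] <- sum(drop)
      df <- df[!drop, , drop = FALSE]
    }
    if (config$min_engines > 1L && nrow(df)) {
      n_eng <- lengths(strsplit(df$engines, ";", fixed = TRUE))
      drop <- n_eng < config$min_engines
      audit["too_few_engines"] <- sum(drop)
      df <- df[!drop, , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  structure(list(peptides = df, audit = audit), class = "filtered_peptides")
}

#' Require missed-cleavage peptides to be supported by sub-peptides
#'
#' A record with one or more missed cleavages is retained only when at
#' least one of its fully cleaved (0-missed) sub-peptides of length
#' `>= min_len` is itself present in the same dataset's filtered set, for
#' the same enzyme (I/L-insensitive comparison). Runs after the
#' specificity/score filters.
#'
#' @param peptides data.frame of filtered records for one dataset, or a
#'   `filtered_peptides` object (its `peptides` element is used and the
#'   audit extended).
#' @param min_len minimum sub-peptide length considered as support.
#' @param proline_rule proline suppression for the sub-digestion.
#' @return A `filtered_peptides` object.
#' @export
enforce_missed_cleavage_support <- function(peptides, min_len = 7L,
                                            proline_rule = TRUE) {
  audit <- c(unsupported_missed = 0L)
  if (inherits(peptides, "filtered_peptides")) {
    audit <- c(peptides$audit, audit)
    peptides <- peptides$peptides
  }
  df <- peptides
  if (nrow(df)) {
    if (is.null(df$n_missed))
      df$n_missed <- mapply(count_internal_sites, df$sequence, df$enzyme,
                            MoreArgs = list(proline_rule = proline_rule))
    zero_by_enz <- split(canonical_il(df$sequence[df$n_missed == 0L]),
                         df$enzyme[df$n_missed == 0L])
    keep <- rep(TRUE, nrow(df))
    for (i in which(df$n_missed >= 1L)) {
      subs <- digest_protein(df$sequence[i], df$enzyme[i], max_missed = 0L,
                             min_len = min_len, proline_rule = proline_rule)
      subs <- subs$peptide[subs$n_missed == 0L]
      keep[i] <- length(subs) > 0L &&
        any(canonical_il(subs) %in% zero_by_enz[[df$enzyme[i]]])
    }
    audit["unsupported_missed"] <- sum(!keep)
    df <- df[keep, , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(list(peptides = df, audit = audit), class = "filtered_peptides")
}

#' Keep peptides replicated across experiments
#'
#' Retains canonical (I/L-collapsed) peptide sequences observed in at least
#' `min_datasets` distinct datasets after per-dataset filtering, merging
#' provenance. Peptides seen in a single experiment are the most likely
#' false positives and are excluded by default.
#'
#' @param per_dataset_sets named list (by dataset id) of
#'   `filtered_peptides` objects or plain record data.frames.
#' @param min_datasets minimum number of distinct datasets.
#' @return data.frame with one row per surviving canonical peptide:
#'   `canon_seq`, `sequence` (a representative raw sequence), `datasets`
#'   (`;`-joined), `n_datasets`, `enzymes` (`;`-joined), `n_missed` (min
#'   across records).
#' @export
cross_experiment_filter <- function(per_dataset_sets, min_datasets = 2L) {
  if (min_datasets > length(per_dataset_sets))
    stop("min_datasets (", min_datasets, ") exceeds number of datasets (",
         length(per_dataset_sets), ")", call. = FALSE)
  recs <- lapply(per_dataset_sets, function(x) {
    if (inherits(x, "filtered_peptides")) x$peptides else x
  })
  all <- do.call(rbind, lapply(recs, function(d)
    d[, intersect(c("sequence", "dataset", "enzyme", "n_missed"), names(d)),
      drop = FALSE]))
  if (is.null(all) || !nrow(all))
    return(data.frame(canon_seq = character(), sequence = character(),
                      datasets = character(), n_datasets = integer(),
                      enzymes = character(), n_missed = integer(),
                      stringsAsFactors = FALSE))
  all$canon_seq <- canonical_il(all$sequence)
  sp <- split(all, all$canon_seq)
  out <- lapply(sp, function(d) {
    ds <- sort(unique(d$dataset))
    data.frame(canon_seq = d$canon_seq[1],
               sequence = d$sequence[1],
               datasets = paste(ds, collapse = ";"),
               n_datasets = length(ds),
               enzymes = paste(sort(unique(d$enzyme)), collapse = ";"),
               n_missed = min(d$n_missed),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[res$n_datasets >= min_datasets, , drop = FALSE]
  rownames(res) <- NULL
  res
}
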