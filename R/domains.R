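#' Read per-isoform domain annotations
#'
#' Accepts the tabular output of standard domain scanners: a TSV with
#' columns `isoform_id`, `domain_acc`, `start`, `end` (1-based protein
#' coordinates).
#'
#' @param path TSV file path.
#' @return data.frame of domain annotations.
#' @export
read_domain_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("isoform_id", "domain_acc", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("domain table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

overlap_len <- function(s1, e1, s2, e2) max(0L, min(e1, e2) - max(s1, s2) + 1L)

#' Effect of a splice event on domain annotations
#'
#' Compares the domain content of the main and alternative isoforms around
#' one splice event and returns a single verdict:
#' \describe{
#'   \item{swap}{the domain accessions over the event region differ as
#'     multisets, with domains present on both sides — one set replaced by
#'     another.}
#'   \item{broken}{a main-isoform domain overlapping the event loses or
#'     gains five or more residues in the alternative without disappearing
#'     entirely.}
#'   \item{lost}{at least one whole domain is absent from the alternative
#'     while the remaining domains are intact.}
#'   \item{none}{otherwise. A homologous substitution coinciding with a
#'     domain is counted as none ("unbroken") unless the domain accession
#'     is listed in `break_overrides` — homologous replacement preserves
#'     the fold.}
#' }
#' Domain identity across isoforms is matched by accession and ordinal
#' occurrence outside the event, so pure coordinate shifts from upstream
#' indels do not count as loss.
#'
#' @param event a classified `splice_event`.
#' @param main_domains,alt_domains data.frames of domain intervals for the
#'   two isoforms (own protein coordinates): columns `domain_acc`,
#'   `start`, `end`.
#' @param break_overrides character vector of domain accessions for which
#'   the homologous-substitution exemption is lifted.
#' @return list with `verdict` (one of `"broken"`, `"lost"`, `"swap"`,
#'   `"none"`) and `details`.
#' @export
event_domain_effect <- function(event, main_domains, alt_domains,
                                break_overrides = character()) {
  empty <- data.frame(domain_acc = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  md <- if (is.null(main_domains) || !nrow(main_domains)) empty else main_domains
  ad <- if (is.null(alt_domains) || !nrow(alt_domains)) empty else alt_domains
  md <- md[order(md$start, -(md$end - md$start)), , drop = FALSE]
  ad <- ad[order(ad$start, -(ad$end - ad$start)), , drop = FALSE]

  seg_m <- event$main_segment %||% c(event$main_flank[1], event$main_flank[1] + 1L)
  seg_a <- event$alt_segment %||% c(event$alt_flank[1], event$alt_flank[1] + 1L)
  delta <- (if (is.null(event$alt_segment)) 0L else
              event$alt_segment[2] - event$alt_segment[1] + 1L) -
           (if (is.null(event$main_segment)) 0L else
              event$main_segment[2] - event$main_segment[1] + 1L)

  over_m <- md[mapply(overlap_len, md$start, md$end,
                      MoreArgs = list(s2 = seg_m[1], e2 = seg_m[2])) > 0L, ,
               drop = FALSE]
  over_a <- ad[mapply(overlap_len, ad$start, ad$end,
                      MoreArgs = list(s2 = seg_a[1], e2 = seg_a[2])) > 0L, ,
               drop = FALSE]

  verdict <- "none"
  details <- character()

  hes_exempt <- identical(event$kind, "homologous_substitution")

  # swap: event region's accession multisets differ, both sides populated
  acc_m <- sort(over_m$domain_acc)
  acc_a <- sort(over_a$domain_acc)
  if (length(acc_m) && length(acc_a) && !identical(acc_m, acc_a)) {
    if (!hes_exempt || any(c(acc_m, acc_a) %in% break_overrides))
      return(list(verdict = "swap",
                  details = paste0(paste(acc_m, collapse = "+"), " -> ",
                                   paste(acc_a, collapse = "+"))))
  }

  # match main domains to alt domains: accession + ordinal among same-acc
  match_key <- function(d) {
    if (!nrow(d)) return(character())
    paste0(d$domain_acc, "#", stats::ave(seq_len(nrow(d)), d$domain_acc,
                                         FUN = seq_along))
  }
  md$key <- match_key(md)
  ad$key <- match_key(ad)

  broken <- FALSE; lost <- FALSE
  for (r in seq_len(nrow(md))) {
    ov <- overlap_len(md$start[r], md$end[r], seg_m[1], seg_m[2])
    if (ov == 0L) next
    exempt <- hes_exempt && !(md$domain_acc[r] %in% break_overrides)
    in_alt <- md$key[r] %in% ad$key
    if (!in_alt) {
      lost <- TRUE
      details <- c(details, paste0("lost:", md$domain_acc[r]))
      next
    }
    # size change of the surviving domain
    a <- ad[ad$key == md$key[r], , drop = FALSE][1, ]
    len_m <- md$end[r] - md$start[r] + 1L
    len_a <- a$end - a$start + 1L
    if (abs(len_a - len_m) >= 5L && !exempt) {
      broken <- TRUE
      details <- c(details, paste0("broken:", md$domain_acc[r]))
    }
  }
  if (broken) verdict <- "broken"
  else if (lost) verdict <- "lost"
  list(verdict = verdict, details = details)
}

#' Tally domain effects over a set of events
#'
#' @param events list of classified `splice_event`s (deduplicated).
#' @param domain_annotations data.frame of per-isoform domain intervals
#'   (columns `isoform_id`, `domain_acc`, `start`, `end`).
#' @param break_overrides see [event_domain_effect()].
#' @return list with `counts` (named: broken, lost, swap, none),
#'   `percentages` (summing to 100) and per-event `verdicts`.
#' @export
tally_domain_effects <- function(events, domain_annotations,
                                 break_overrides = character()) {
  dom_of <- function(iso)
    domain_annotations[domain_annotations$isoform_id == iso, , drop = FALSE]
  verdicts <- vapply(events, function(ev)
    event_domain_effect(ev, dom_of(ev$main_isoform_id),
                        dom_of(ev$alt_isoform_id),
                        break_overrides)$verdict, character(1))
  lev <- c("broken", "lost", "swap", "none")
  counts <- vapply(lev, function(l) sum(verdicts == l), integer(1))
  list(counts = counts,
       percentages = count_percentages(counts),
       verdicts = verdicts)
}

#' Percentages from category counts
#'
#' The reporting arithmetic used for event-kind and domain-impact
#' summaries: `100 * x / sum(x)`.
#'
#' @param x non-negative numeric vector of counts (possibly named).
#' @return numeric vector of percentages summing to 100.
#' @export
count_percentages <- function(x) {
  stopifnot(all(x >= 0), sum(x) > 0)
  100 * x / sum(x)
}
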