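---
title: "Detecting alternative splicing at the protein level: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting alternative splicing at the protein level: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicepep)
```

## The problem

Transcriptomics finds alternatively spliced mRNAs for almost every
multi-exon gene, but shotgun proteomics finds protein-level evidence for
only a small fraction of the annotated isoforms. Deciding whether a gene
expresses more than one protein isoform from peptide-spectrum evidence is
delicate: most peptides are shared between isoforms, search engines
produce false positives at exactly the rate that matters for rare
alternative peptides, and the interesting signal often rests on a single
discriminating peptide. `splicepep` implements a conservative pipeline
for this decision, plus the surrounding analyses — event taxonomy,
mutually exclusive homologous exon detection, domain-impact scoring,
evolutionary dating, and in-silico null models that quantify how much
alternative splicing one *would* see if isoforms were co-expressed.

## High-confidence peptide sets

Peptide tables from heterogeneous experiments are filtered per dataset:

* **Enzyme specificity.** Non- and semi-specific peptides are removed.
  A terminus conforms when the flanking residue matches the enzyme rule
  (trypsin: K/R, LysC: K, chymotrypsin: F/W/Y, GluC: E/D), with protein
  termini (`prev_aa`/`next_aa` = `-`) conforming by definition, and
  cleavage before proline suppressed by default. Because specificity
  cannot be judged from the bare sequence, tables carry the flanking
  residues; when they are absent the termini are assumed conforming and a
  warning is raised.
* **Scores and engines.** Each dataset has its own score scale and
  threshold (e.g. an Andromeda-style cut-off of 100) and may require
  agreement of two or more search engines. Scores are never compared
  across datasets.
* **Missed-cleavage support.** A peptide with missed cleavages is kept
  only when one of its fully cleaved sub-peptides (at least `min_len`
  residues, same enzyme, I/L-insensitive) is present in the same
  dataset's filtered set. Support is checked within-dataset because
  cross-dataset support would let one experiment's artifact rescue
  another's.
* **Cross-experiment replication.** Only peptides seen in at least two
  datasets are mapped. This is the single most aggressive filter and is
  the package's main defence against false-positive identifications.

All sequence comparisons are performed on I/L-collapsed strings
(`canonical_il()`), since isoleucine and leucine are isobaric.

## Mapping and the main isoform

Peptides are matched to isoform proteins by exact substring search after
canonicalization. Peptides hitting two or more genes are discarded; a
peptide is isoform-discriminating when it maps to a proper subset of its
gene's isoforms. Each gene's *main isoform* is the one with the most
discriminating peptides (ties: principal flag, longest protein,
lexicographic id); without peptide evidence the principal isoform is
used, taken from a curated table when supplied and otherwise the longest
protein. Splice events are always defined main-vs-alternative.

## Event extraction and the seven kinds

Two isoforms of a gene are projected onto each other by genomic codon:
two protein positions match when they are encoded by the same three
genomic nucleotides read in the same frame. This makes frame shifts over
shared exons visible (no matched positions, hence a two-protein pair)
and needs no alignment heuristics; a global protein alignment is the
fallback when CDS coordinates are missing. Maximal unmatched runs become
events, classified as:

| kind | rule |
|---|---|
| `two_proteins` | no matched positions at all |
| `nagnag` | pure insertion/deletion of at most 4 residues |
| `indel` | pure insertion/deletion of more than 4 residues |
| `homologous_substitution` | both segments present and significantly homologous |
| `nterm_substitution` / `cterm_substitution` | non-homologous substitution touching the first / last position |
| `internal_substitution` | any other substitution |

The homology check precedes the terminal labels, so homologous swaps of
first or last exons count as homologous substitutions. Alternative
proteins that are exact prefixes or suffixes of the main protein are
treated as annotation fragments (truncations) and emit no events. When a
substitution touches both termini the longer unmatched terminus decides
the label. Events are deduplicated on (gene, kind, genomic span), so the
same exon skip seen in several isoform pairs is counted once.

**Homology significance.** Segment homology is scored by local alignment
(BLOSUM62, gap open 10, extend 1) and assessed against 200
composition-preserving shuffles of the second segment. The empirical
p-value floor is 1/201 ≈ 0.00498, so the default threshold of 0.005
demands that the true alignment beat every shuffle. This replaces a
database e-value — there is no sequence database in scope — while keeping
the same operating point; on unrelated random segments the test fires at
about the 0.5% rate its threshold implies. Segments shorter than two
residues are never called homologous.

## Identified splicing events (ISEs)

An event becomes an ISE only with peptide evidence on *both* sides:

* an inserted or substituted segment needs a pair-specific peptide
  overlapping it by at least one residue;
* the deleted side needs a peptide on the shorter isoform spanning the
  junction with at least one residue on each flank.

A consequence of the junction rule is that pure terminal
insertions/deletions cannot be evidenced on the short side (the junction
has a single flank); such events never become ISEs. Peptides shared by
both isoforms of the pair never count for either side.

## Mutually exclusive homologous exons (HES)

Independently of peptide data, `scan_hes()` searches each multi-isoform
gene for CDS exon pairs that (i) never co-occur in an annotated
transcript, (ii) are each longer than 30 bp, and (iii) do not overlap
genomically — overlapping "pairs" are length variants of a single exon
(tandem splice sites), not mutually exclusive exons. Candidates are
verified when their translations pass the homology test, their midpoints
fall at equivalent relative positions in the host proteins (within 10%
of protein length — the threshold replaces manual inspection of
alignments), and neither exon lies far outside the span of the gene's
other exons (a guard against exons actually belonging to a paralogous
neighbour or pseudogene; "far" means beyond the larger of 10 kb and the
gene's own span). Any verified pair, run through the event module on its
host transcripts, classifies as a homologous substitution — the two
modules are consistent by construction and this is tested.

## Domain impact

Per-isoform domain intervals (the tabular output of standard domain
scanners) are compared around each event. A domain is *broken* when it
loses or gains five or more residues without disappearing, *lost* when it
is absent from the alternative while the remaining domains stay intact,
and the verdict is *swap* when the accession multisets over the event
region differ with domains on both sides. A homologous substitution
coinciding with a domain is deliberately counted as *none*: homologous
replacement preserves the fold. A per-accession override list lifts this
exemption for poorly delimited domains. Domains are matched across
isoforms by accession and ordinal occurrence, so coordinate shifts from
upstream indels are not mistaken for losses; a known limitation is that
ordinal matching can pair the wrong copies when a multi-copy domain
family is itself truncated.

## Null abundance models

How much alternative splicing would the experiments have seen if
alternative isoforms were actually present? The package digests the gene
set in silico (fully tryptic, no missed cleavages, at least seven
residues — missed-cleavage combinations would explode the space),
deduplicates peptides, and draws per gene exactly as many peptides as
the real analysis identified for that gene, without replacement, with
probability proportional to a model weight:

* **uniform** — every peptide weight 1 (all isoforms expressed equally);
* **dominant** — weight `ratio × [in principal] + #alternative isoforms
  containing it`, default ratio 50.

A gene counts as an AS gene in a replicate when the drawn set satisfies
the same both-sides rule used for observed ISEs (including the junction
rule), so the null and observed analyses are commensurable. "Three or
more isoforms" is implemented as at least two distinct alternative
isoforms each evidenced against the main isoform; a full pairwise
partition over all isoform pairs was considered and rejected as an
over-engineered proxy for the same quantity at these gene sizes. Means
are taken over 100 replicates by default; a fixed seed gives
bit-identical output.

## Evolutionary dating

Cross-species similarity hits (precomputed, BLAST-style tables) are
assigned to annotated genes when they fall within a window equal to the
95th percentile of the target species' gene lengths, remaining hits
being clustered into new loci by single linkage under the same window.
Presence/absence of a feature across species is dated by Dollo parsimony
— a character is gained once and lost freely, so the origin is the most
recent common ancestor of the taxa that have it. Enrichment questions
(e.g. are HES genes over-represented among detected genes?) use an exact
hypergeometric test; the two-sided p sums all tables with probability at
most that of the observed table, and the odds ratio is the sample odds
ratio with a 0.5 continuity correction when a cell is zero.

## The synthetic study system

Because the real inputs are tens of gigabytes of external data, the
package ships a generator that emulates their structure with known
ground truth. Design choices, made once:

* 200 genes, 20% single-isoform, multi-isoform genes carrying 1–3
  alternatives (75/15/10%); each alternative differs from the main
  isoform by exactly one planted event. Event kinds follow the observed
  event mix (38.7% indel, 13.8% NAGNAG, 21.3% homologous substitution,
  15.2% C-terminal, 8.5% N-terminal, 0.7% internal, 1.8% two-protein),
  apportioned exactly by largest remainder.
* Proteins are sampled with a combined K/R frequency of 0.11, giving
  tryptic peptides of realistic length (median near 9), and
  reverse-translated codon-by-codon; minus-strand genes are generated at
  30%. Homologous exon pairs are mutated copies at 80–95% identity
  (comfortably above the homology-test threshold, so classification is
  unambiguous); two-protein pairs share an exon read in shifted frame,
  built from T-free codons so both frames are stop-free.
* One UGT1A-style cluster: member "genes" share common 3' exons joined
  to distinct homologous first exons, plus read-through decoy
  transcripts and pseudoautosomal decoy genes for the loader filters.
* Detection: gene abundance is log-normal (meanlog −0.5, sdlog 1.5), the
  principal isoform is expressed 50× each alternative, and a peptide of
  abundance *a* is seen in an experiment with probability
  1 − exp(−1.2 a) (missed-cleavage peptides at 0.3 of that). These
  values were chosen so that roughly two thirds of genes are detected
  with ≥2 peptides and alternative-isoform peptides are rare —
  the regime the method is designed for.
* Artifacts are injected at 1% of the clean record count per class
  (non-tryptic substrings, unsupported missed cleavages,
  single-experiment peptides, sub-threshold scores), each constructed so
  that exactly one filter is responsible for removing it, and each
  labelled in the truth tables.

What the generator does **not** emulate: spectral detectability
physics (hydrophobicity, charge, flyability), correlated detection
across experiments, shared peptides between paralogous genes, PTMs, and
decoy-based FDR structure. Passing tests on synthetic data therefore
certify the pipeline's logic — filters remove what they should, events
classify as defined, the null models rank as expected — not the
biological accuracy of any particular real-data count.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally, 1-based inclusive in GTF
  and 1-based in protein space; minus-strand CDS are reverse-complemented
  exon-by-exon in transcription order before translation.
* `fisher_exact` compares probabilities with a 1 + 1e−7 relative slack
  when summing the two-sided tail, matching standard practice, and
  errors on zero margins.
* Draws larger than a gene's peptide universe draw everything and warn.
* Empty event sets, genes without peptides, single-isoform genes, and
  peptide tables with zero rows all pass through the pipeline without
  special-casing by the caller.
* All stochastic internals (shuffles, draws, the generator) run under
  locally scoped seeds and restore the caller's RNG state.

## Problem sizes

The test-suite and acceptance runs use a 200-gene genome with eight
simulated experiments (roughly 6,000 peptide records), 100 replicates
per null model, an exhaustive Fisher sweep over all 2×2 tables with
N ≤ 60, 1,000 random proteins for the digestion oracle, and 50 dated
features on a six-taxon vertebrate tree. These sizes were chosen as the
smallest at which every planted structure appears with comfortable
multiplicity.

## Worked example

```{r example, eval = FALSE}
syn <- generate_gene_set(n_genes = 200, seed = 1)
det <- simulate_detections(syn, seed = 2)
fit <- splice_scan(syn$gene_set, det$tables,
                   dataset_configs = det$configs,
                   clusters = syn$truth$clusters,
                   domain_annotations = syn$truth$domains)
summary(fit)
simulate(fit, nsim = 100, seed = 3, model = "dominant", ratio = 50)
```

## Known limitations

* Exact substring matching cannot tolerate sequence variants or PTMs.
* The fallback projection for isoforms without CDS coordinates counts
  aligned identical residues as matched, which can fragment events in
  highly diverged regions.
* The HES midpoint-equivalence threshold (10% of protein length) is a
  deterministic stand-in for expert inspection and will mis-rank
  pathological gene models.
* Dollo dating assumes losses are free; convergent exon gain would be
  dated too early.
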