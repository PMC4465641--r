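Package: splicepep
Title: Peptide-Level Evidence for Alternative Splicing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for assessing alternative splicing at the protein level
    from large-scale proteomics peptide identifications. Filters peptide
    tables to a high-confidence set (enzyme specificity, search-engine
    agreement, score thresholds, missed-cleavage support, cross-experiment
    replication), maps peptides to isoform annotations with
    isoleucine/leucine-insensitive matching, extracts and classifies splice
    events between main and alternative isoforms (indels, NAGNAG, homologous
    and non-homologous substitutions, two-protein pairs), detects events with
    peptide evidence on both sides, scans annotations for mutually exclusive
    homologous exons, scores the impact of events on protein domain
    annotations, dates exon origins by Dollo parsimony, and quantifies the
    expected-versus-observed gap with in-silico tryptic digestion null
    models. Includes a synthetic-data generator with full ground truth so
    every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    ape,
    methods,
    rtracklayer,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    withr,
    yaml
Config/testthat/edition: 3
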