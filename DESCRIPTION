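Package: allerscan
Title: Phage-Display Allergen Serology: Library Design, Enrichment Calling and Repertoire Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete analysis toolkit for phage immunoprecipitation
    sequencing (PhIP-Seq) of allergen peptide libraries. Designs tiled
    peptide libraries from allergen protein FASTA files (56-aa tiles with
    28-aa overlaps, codon-optimised oligonucleotide synthesis with
    restriction-motif avoidance), counts sequencing reads by exact match
    against library inserts, models the mock-immunoprecipitation null with
    a negative binomial distribution and calls enriched peptides ("hits")
    by count, p-value and fold-change thresholds, measures antibody
    repertoire breadth as a maximal independent vertex set in a peptide
    sequence-homology graph, and provides cohort-level analytics:
    prevalence and organism filters, hierarchical clustering, Wilcoxon
    group and paired comparisons, IgE/IgG isotype concordance, epitope
    summaries and longitudinal oral-immunotherapy change analysis. A
    seeded synthetic-cohort generator with exported ground truth makes
    every stage testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    igraph,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
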