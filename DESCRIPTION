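Package: phagecub
Title: Codon Usage Bias and Genomic Heterogeneity Across Bacteriophage Lifestyles
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis of bacteriophage lifestyles (virulent,
    temperate, prophage) from coding sequences and pairwise genome similarity.
    Computes per-gene compositional and codon-usage metrics (gene length,
    overall and position-specific GC content, the Codon Adaptation Index of
    Sharp and Li, and Wright's effective number of codons), a combined genomic
    distance over BLAST-style similarity tables with explicit handling of
    genome pairs lacking detectable similarity, and a full nonparametric
    statistical ledger: Kruskal-Wallis tests with rank-based eta- and
    epsilon-squared effect sizes, Dunn's post-hoc contrasts, Mann-Whitney
    tests with Cliff's delta, Holm and Benjamini-Hochberg corrections,
    bootstrap and partial Spearman correlations, the Scheirer-Ray-Hare test,
    and permutation-based multivariate location and dispersion tests
    (PERMANOVA and PERMDISP). A lifestyle-structured synthetic-data generator
    makes the whole pipeline testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
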