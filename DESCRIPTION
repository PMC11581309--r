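Package: cadevo
Title: Comparative Molecular Evolution of Classical Cadherins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pairwise comparative-evolution analysis of classical cadherin
    (CDH) orthologs: amino-acid divergence under the Jones-Taylor-Thornton
    (JTT) model, codon-level synonymous/nonsynonymous divergence by the
    degeneracy-class (Pamilo-Bianchi-Li/Kumar) estimator with Kimura
    two-parameter corrections, codon-based Z and Fisher exact tests of
    selection, domain-partitioned comparisons, gene-essentiality scoring,
    expression-level versus evolutionary-rate (E-R) Spearman profiling, and
    nonparametric group comparisons (Kruskal-Wallis, Dunn with Holm
    adjustment, Mann-Whitney U). Includes seeded simulators for diverging
    codon sequences, domain-structured ortholog sets, expression matrices
    with planted rank correlations, and phenotype records, so the whole
    pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
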