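Package: exonedge
Title: Exon-Edge Conservation Effects on dN/dS and the Neutrality Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counting-based molecular evolution pipeline for studying how
    conservation at exon edges (exonic splicing enhancer regions) biases
    estimates of dN/dS and the McDonald-Kreitman-style neutrality index, and
    their correlations with gene expression. Implements Nei-Gojobori (1986)
    pairwise dN/dS with Jukes-Cantor correction, lineage-specific per-branch
    dN/dS on three-taxon trees via codon parsimony, SNP-based polymorphism
    classification and a pseudo-count neutrality index, sequential exon-edge
    codon trimming with matched random-removal randomization tests, expression
    covariates (tau, breadth, Z-scores), a transcript-number-normalised
    alternative-splicing index, a correlation battery (Spearman, partial
    Spearman, dependent-correlation comparison, chi-square proportion shifts,
    Kruskal-Wallis), and a ground-truth synthetic orthologue-trio simulator
    that makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
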