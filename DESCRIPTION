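Package: mitocomp
Title: Comparative Mitochondrial Genome Composition and Gene-Order Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated animal mitochondrial
    genomes: nucleotide composition with Perna-Kocher AT- and GC-skews,
    per-gene and per-codon-position profiles, codon and codon-family usage,
    breakpoint distances and conserved blocks between circular signed gene
    orders, chi-square homogeneity and matched-pairs (Bowker) symmetry tests
    of compositional heterogeneity, posterior-predictive-style amino acid
    deviation statistics against simulated nulls, amino acid recoding
    (Dayhoff groups and minmax chi-squared bins), and sitewise evolutionary
    rate estimation under a discrete-gamma model on a fixed tree with removal
    of the fastest-evolving sites. Includes simulators for rearranged gene
    orders, tree-structured sequence evolution with stationary or
    branch-shifted composition, and codon streams with prescribed usage, so
    every stage can be exercised on synthetic data.
License: MIT + file LICENSE
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    Matrix,
    jsonlite
Encoding: UTF-8
Config/testthat/edition: 3
RoxygenNote: 7.3.3
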