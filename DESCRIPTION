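Package: atropomine
Title: Machine-Learning Genome Mining for Atropopeptide Biosynthetic Gene
    Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering atropopeptide biosynthetic gene clusters
    in bacterial genomes. A random-forest classifier recognises
    atropopeptide-modifying cytochrome P450s from reduced-alphabet 4-mer
    features computed on functional regions delimited by alignment to an
    annotated reference P450. A deterministic short-ORF finder then scans
    the genomic neighbourhood of positive P450 genes for precursor-peptide
    genes using core-aromaticity and leader-motif rules, and elemental
    formula arithmetic predicts protonated monoisotopic masses of
    crosslink-modified core peptides for screening culture extracts by
    high-resolution mass spectrometry. Seeded generators provide synthetic
    protein families and GenBank neighbourhoods with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ranger,
    jsonlite,
    withr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
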