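Package: pgptProfiler
Title: Functional Profiling of Plant-Growth-Promoting-Trait Genes in
    Shotgun Metagenomes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for threshold-based homology screening of shotgun
    metagenome reads against a curated catalog of plant-growth-promoting
    trait (PGPT) genes. Implements host-read removal by best-nucleotide-hit
    taxonomy, strict E-value/length/identity screening of tabular homology
    search results, a gene-length-normalized detection-frequency statistic
    expressed per 100,000 reads, best-hit taxonomic relative abundance with
    rank-wise "Others" pooling, Monte-Carlo rarefaction, neighbor-joining
    phylogenetic typing of methanol dehydrogenase reads (xoxF versus mxaF)
    with an outgroup-clade rule, and a two-sample t-test for delta-15N
    isotope tracer experiments. A seeded synthetic-data generator produces
    reference gene families, pyrosequencing-like reads with truth labels,
    and structured hit tables so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
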