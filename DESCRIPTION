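Package: parasnv
Title: Shared SNV Analysis for Detecting Gene Flow Between Spatially
    Segregated Microbial Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect gene flow and homologous recombination between
    closely related, spatially segregated microbial populations from
    metagenome-assembled genomes (MAGs). Implements curated single nucleotide
    variant (SNV) calling from mapped read-pair observations, greedy protein
    clustering to define homologous sites across genomes, hierarchical
    identification of SNVs shared by MAG pairs and triplets, an exact
    combinatorial null model (12/16^k) for the probability that independent
    populations converge on the same substitution at the same site,
    fragment-based contig-pair average nucleotide identity, and pairwise
    identity matrices for mobile genetic elements. A synthetic-data generator
    emulates a two-clade, three-depth borehole scenario so that every stage is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    data.table,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
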