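Package: isgfinder
Title: Sequence, Network and Machine-Learning Characterisation of
    Interferon-Stimulated Genes
Version: 0.1.0
Authors@R:
    person("isgfinder", "developers", email = "isgfinder@example.org",
           role = c("aut", "cre"))
Description: Encodes interferon-stimulated human genes (ISGs) from coding
    sequences, protein sequences and a protein-protein interaction network:
    nucleotide, dinucleotide, 4-mer and synonymous codon-usage compositions;
    amino-acid and physicochemical group compositions; eight per-node network
    centrality metrics; and degenerate short linear nucleotide/amino-acid
    pattern mining with chi-squared enrichment and Benjamini-Hochberg
    correction. Quantifies feature association with interferon stimulation
    through a fold-change-binned correlation statistic and trains an RBF-SVM
    classifier with an AUC-driven subtractive feature-elimination algorithm,
    alongside KNN and random-forest comparators. Ships a seeded synthetic
    benchmark generator (planted GC gap, planted motifs, feature-linked fold
    changes, scale-free interactome) so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    igraph,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
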