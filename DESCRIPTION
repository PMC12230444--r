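Package: repliMir
Title: Replication-Timing Domain Analysis of miRNA Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Comparative analysis of microRNAs located in early- versus
    late-DNA-replication temporal domains. Provides S/G1 replication-timing
    normalization and early/late domain calling, a simplified nearest-neighbour
    RNA folding engine (minimum free energy, partition function, ensemble
    diversity and neutral set size), hairpin element and energy-term
    decomposition, flanking-sequence GC profiling and orthologue fold-potential
    filtering, Dicer cleavage-motif extraction with edit-distance MDS
    clustering, CAGE-based promoter calling via a semi-supervised Gaussian
    mixture with GLM priors, degree-preserving edge-swap network null models
    with Z-score statistics, tissue-expression statistics (tau specificity),
    an RBF-SVM replication-timing classifier, and seeded synthetic-data
    generators with ground truth for every pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    limma,
    e1071,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
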