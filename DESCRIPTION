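Package: interolog
Title: Conserved Interolog Protein Network Reconstruction Across Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs the evolutionarily conserved interolog protein
    network (IPN) shared by two to four species. Orthology between each
    species pair is inferred by reciprocal best hits under Needleman-Wunsch
    global alignment with affine gap penalties; network nodes are sets of
    mutually orthologous proteins (OPS), one protein per species; edges
    connect OPS pairs whose member proteins interact in at least a
    user-chosen number of the species' interaction networks (the coverage
    cutoff). Per-species networks are read from STRING-style weighted edge
    lists and filtered by combined confidence score. Includes a
    deterministic synthetic-data generator with known ground-truth
    orthology for validation, and TSV/GraphML/DOT exporters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports: methods, stats, utils, tools, Biostrings, igraph, yaml, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, jsonlite, withr
Config/testthat/edition: 3
biocViews: NetworkInference, Alignment, GraphAndNetwork
RoxygenNote: 7.3.3
Collate: 
    'interolog-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'alignment.R'
    'ppin.R'
    'seqio.R'
    'fixtures.R'
    'orthology.R'
    'ops.R'
    'ipn.R'
    'writers.R'
    'pipeline.R'
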