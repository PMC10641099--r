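Package: pcnet
Title: Protein Contact Networks: Construction, Centrality, Clustering and Node Roles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds protein contact networks (binary residue adjacency
    matrices) from PDB structures using alpha-carbon, beta-carbon or
    residue-centroid representations and a Euclidean distance window, or
    loads precomputed adjacency matrices from a plain-text dialect.
    Provides centrality analysis (degree, betweenness, closeness,
    eigenvector), spectral clustering on three graph-Laplacian variants,
    clustering on low-dimensional node embeddings (Laplacian eigenmaps and
    Katz-index factorization), community extraction (Louvain, greedy
    modularity, label propagation, Girvan-Newman), Newman modularity, and
    per-node participation coefficients and intramodular z-scores.
    Results export as tab-separated tables and as B-factor-annotated PDB
    files ready for molecular viewers; a command-line front end with a
    JSON-lines session journal orchestrates build, analysis and export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
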