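Package: cloneTree
Title: Joint Clone Identification and Intra-Tumor Phylogeny Reconstruction
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Bayesian nonparametric reconstruction of intra-tumor phylogenies
    from binary marker matrices (CpG methylation patterns or single-cell SNV
    genotypes). Observed sequences are clustered into clones that occupy both
    inner and leaf nodes of a phylogenetic tree, using a tree-structured
    stick-breaking process prior over clone sizes and a two-state
    continuous-time Markov chain evolution model linking parent and child
    clone parameters. Inference is by Markov chain Monte Carlo with a
    swap-clone move; posterior clusterings are summarised by maximising the
    posterior expected adjusted Rand index, and maximum a posteriori trees
    are selected by grouping samples on the number of large clones. Includes
    a benchmark simulator for five canonical modes of tumor evolution,
    distance-based baseline pipelines (hierarchical clustering and
    k-centroids with silhouette model selection, Hamming minimum spanning
    trees), and evaluation metrics (v-measure, consensus node-based shortest
    path tree distance, tree summary statistics).
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, cluster, igraph, jsonlite
Suggests: testthat (>= 3.0.0), ape, Matrix, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Phylogenetics, Clustering, Bayesian, DNAMethylation, SingleCell
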