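Package: netquery
Title: Biological Network Querying via Context-Sensitive Random Walks and
    Conductance Minimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Finds the subnetwork of a large protein-protein interaction
    (PPI) network that best matches a smaller query module from another
    species. Node correspondence between the query and target networks is
    estimated with a context-sensitive random walk over node pairs that
    combines interaction topology with sequence-similarity scores; a seed
    set selected from the normalized correspondence matrix is grown
    greedily to minimize network conductance and then pruned by per-node
    extension-reward scores. Includes the matching-score, information-
    content and hypergeometric-enrichment metrics used to evaluate
    predicted complexes, and a synthetic benchmark generator that implants
    a perturbed copy of the query into a random background network with
    known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
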