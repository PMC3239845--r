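Package: netdiff
Title: Differential Clustering of Paired Weighted Networks via the
    Generalized Singular Value Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers clusters of nodes that are strongly connected in one
    weighted network but not in a second network defined on the same node set.
    The two symmetric weight matrices are factorized jointly with the
    Generalized Singular Value Decomposition (GSVD); sorting the components of
    the extreme columns of the inverse-transpose of the shared right factor
    reorders both networks so that condition-exclusive clusters become
    contiguous blocks. Candidate clusters are scored by within-block edge
    density (binary graphs) or mean within-block weight (weighted graphs) and
    assigned Monte-Carlo p-values under node-permutation and graph-randomization
    null models. For two-group metabolomics studies the package builds the pair
    of within-group Pearson correlation networks (optionally Fisher
    z-transformed) from a peak-intensity table, screens individual metabolites
    for overt change, and tests KEGG pathway over-representation in significant
    clusters with the upper-tail hypergeometric probability. Includes synthetic
    generators for planted-cluster binary network pairs and signal-mixing
    correlation network pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
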