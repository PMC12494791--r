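Package: polyentropy
Title: Degree-Based Topological Indices and Edge-Entropies of Polymer Chain Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes degree-based topological indices (first and second Zagreb,
    redefined Zagreb, atom-bond connectivity and geometric-arithmetic) and the
    Shannon edge-entropies they induce for n-unit polyester and polycarbonate
    chain graphs, represented either as explicit molecular graphs or as symbolic
    degree-based edge partitions whose class frequencies are linear in the unit
    count n. Provides exact-rational closed forms a*n + b for the rational
    indices, entropy closed forms ln I(n) - S(n)/I(n), logarithmic regression of
    entropy on index, an audit comparing recomputed closed-form coefficients
    against previously reported ones, and seeded generators of random bounded-
    degree molecular graphs and realizable symbolic partitions for property
    testing. Chain graphs are assembled from built-in repeat-unit templates and
    validated against the symbolic partitions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, igraph, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'rational.R'
    'AllClasses.R'
    'AllGenerics.R'
    'linearform.R'
    'partitions.R'
    'graphs.R'
    'templates.R'
    'indices.R'
    'entropy.R'
    'regression.R'
    'synthetic.R'
    'reported.R'
    'pipeline.R'
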