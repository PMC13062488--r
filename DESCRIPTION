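Package: hypermol
Title: Interpretable Molecular Property Prediction with Hypergraph Attention
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents molecules as hypergraphs whose hyperedges are
    chemically meaningful substructures (SMARTS-matched functional groups,
    ring systems, special motifs, inter-ring connections and isolated-atom
    neighbourhoods), fuses token-level chemical-language embeddings with
    physicochemical atom descriptors, and learns molecular properties with a
    multihead hypergraph attention network trained under Bemis-Murcko
    scaffold splits. Attention coefficients are turned into hyperedge and
    atom importance scores for substructure-level interpretation. Chemistry
    primitives (SMILES parsing, SMARTS matching, descriptors, scaffolds) are
    computed by RDKit through a bundled Python helper; the representation,
    network, training and interpretability machinery are implemented in R.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with the rdkit package, available as
    'python' on the PATH (override with the HYPERMOL_PYTHON environment
    variable).
Config/testthat/edition: 3
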