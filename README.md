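# hypermol

Interpretable molecular property prediction with hypergraph attention
networks, in R.

Standard molecular graph neural networks pass messages along bonds, so
multi-atom units — functional groups, ring systems, inter-ring linkages —
are never represented as wholes, although they often *are* the property-
determining units. `hypermol` represents each molecule as a hypergraph
H = (V, ε): atoms are nodes, and every hyperedge is one chemically
meaningful substructure drawn from five classes (SMARTS-matched functional
groups from a frozen 69-pattern library, SSSR rings and fused ring systems,
special motifs — metal centres, spiro and bridged systems —, ring
connectivity, and a coverage class for leftover atoms). Each hyperedge
carries a 5-dimensional feature vector (chemical type, normalised size,
mean electronegativity, topological centrality, pharmacophore flag); each
atom fuses 15 physicochemical descriptors with token-level semantic
embeddings projected from the SMILES string.

A multihead hypergraph attention network learns on this representation.
Per layer l and head k, with node states h_v and hyperedge features f_e:

    d_ve  = a_v · W_v h_v + a_e · W_e f_e
    α_ve  = softmax over v ∈ e of LeakyReLU(d_ve)        (sums to 1 per edge)
    m_e   = Σ_{v∈e} α_ve (W_v h_v + W_e f_e)             (node → hyperedge)
    m_v   = Σ_{e∋v} α_ve m_e                             (hyperedge → node)
    h_v'  = σ( concat_k m_v^k + b_l )

followed by global mean pooling and a 2-layer MLP. Training uses Adam with
masked losses (missing multi-task labels allowed), early stopping on the
validation loss, and Bemis–Murcko scaffold splitting (80/10/10, stratified
for classification) so structurally similar molecules never leak across
partitions. The attention coefficients double as the interpretability
signal: head-averaged final-layer attention yields hyperedge importance
scores and per-atom relevance heatmap data.

The forward and backward passes are implemented in R (gradients derived
analytically and verified against finite differences); chemistry
primitives (SMILES parsing, SMARTS matching, Gasteiger charges, MW/logP/
TPSA, scaffolds) are delegated to RDKit through a bundled Python helper.

## Requirements and installation

* R ≥ 4.1 with `Matrix` and `jsonlite`
* Python ≥ 3.8 with `rdkit` available as `python` on the PATH
  (override via the `HYPERMOL_PYTHON` environment variable)

```sh
R CMD INSTALL .
```

Run the tests with `Rscript -e 'devtools::test()'` (or
`testthat::test_dir("tests/testthat", package = "hypermol",
load_package = "installed")` against the installed package).

## Worked example

The package ships a fragment-grammar simulator whose labels are known
functions of substructure content — here, hydroxyl count plus noise:

```r
library(hypermol)

sim <- simulate_regression(n = 2000, noise_sd = 0.1, seed = 0)
fit <- hypermol(y ~ smiles, sim, task = "regression",
                control = hgat_control(head_dim = 16, mlp_hidden = 32),
                trainer = trainer_control(epochs = 150, batch_size = 128,
                                          patience = 20),
                seed = 0)
print(fit)
#> <hypermol> multihead hypergraph attention model
#>   task: regression (1 task(s))
#>   architecture: 3 layers x 4 heads x 16 dims; input width 47
#>   split: 1638/200/162 (scaffold)
#>   train rmse: 0.1487
#>   valid rmse: 0.1419
#>   test rmse: 0.1502
```

The test RMSE of about 0.15 sits close to the label noise floor
(σ = 0.1): the network has recovered the hydroxyl count on scaffolds it
never saw during training. Prediction and explanation:

```r
predict(fit, c("OCC(O)CO", "CCCC"))      # predicted hydroxyl counts
ex <- explain(fit, "OCC(O)c1ccccc1")     # attention-derived importances
ex$atom_scores                           # per-atom relevance in [0, 1]
explanation_json(ex, "explanation.json") # heatmap-ready export
```

Hypergraph construction is available on its own:

```r
hg <- build_hypergraph("CC(=O)N")   # acetamide
as.data.frame(hg)
#>   id         category size members     annotation
#> 1  1 functional_group    3   2,3,4          amide
#> 2  2         isolated    2     1,2 neighborhood;1
```

A thin command-line front end wraps the same functions
(`inst/cli/hypermol.R`): `build-graph`, `simulate`, `split`, `train`,
`predict`, `explain`.

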