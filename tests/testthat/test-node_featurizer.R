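test_that("traditional descriptors use the stated normalisers", {
  methane <- traditional_descriptors(parse_molecule("C"))
  expect_equal(ncol(methane), 15)
  expect_equal(unname(methane[1, "z_norm"]), 0.06)
  expect_equal(unname(methane[1, "h_norm"]), 1.0)
  expect_equal(unname(methane[1, "degree_norm"]), 0.0)
  expect_equal(unname(methane[1, c("bond_single", "bond_double", "bond_triple",
                                   "bond_aromatic")]), rep(0, 4))

  benzene <- traditional_descriptors(parse_molecule("c1ccccc1"))
  # all incident bonds aromatic
  expect_equal(unname(benzene[1, c("bond_single", "bond_double", "bond_triple",
                                   "bond_aromatic")]), c(0, 0, 0, 1))
  # MW 78.114 from standard atomic masses
  expect_equal(unname(benzene[1, "mw_norm"]), 78.114 / 500, tolerance = 1e-4)
  # molecule-level triplet identical across atoms
  expect_equal(var(benzene[, "mw_norm"]), 0)
  expect_equal(var(benzene[, "logp_norm"]), 0)
  expect_equal(var(benzene[, "tpsa_norm"]), 0)
})

test_that("bond-type histograms sum to one for every bonded atom", {
  for (s in c("CCO", "CC(=O)N", "c1ccccc1", "C#N", "C1CC2CCC1C2")) {
    mol <- parse_molecule(s)
    td <- traditional_descriptors(mol)
    hist_sum <- rowSums(td[, c("bond_single", "bond_double", "bond_triple",
                               "bond_aromatic"), drop = FALSE])
    bonded <- mol$atoms$degree > 0
    expect_equal(hist_sum[bonded], rep(1, sum(bonded)))
  }
})

test_that("SMILES tokenization separates atom and non-atom tokens", {
  tokens <- tokenize_smiles("CC(=O)[O-]")
  expect_equal(tokens, c("C", "C", "(", "=", "O", ")", "[O-]"))
  expect_equal(tokenize_smiles("Clc1ccccc1Br"),
               c("Cl", "c", "1", "c", "c", "c", "c", "c", "1", "Br"))
})

test_that("token-to-atom mapping assigns atom tokens in order", {
  mol <- parse_molecule("CCO")
  map <- map_tokens_to_atoms(tokenize_smiles("CCO"), mol)
  expect_equal(map$atom_tokens, list(1L, 2L, 3L))
  expect_length(map$unmapped, 0)

  mol2 <- parse_molecule("CC(=O)N")
  map2 <- map_tokens_to_atoms(tokenize_smiles("CC(=O)N"), mol2)
  # "(", "=", ")" map to no atom
  expect_equal(sum(is.na(map2$token_atom)), 3)
  expect_equal(map2$atom_tokens[[3]], 5L) # the O token

  # "##" subtokens inherit the parent's atom
  map3 <- map_tokens_to_atoms(c("C", "##C", "O"), mol)
  expect_equal(map3$atom_tokens[[1]], c(1L, 2L))
})

test_that("token aggregation weights sum to one and reduce correctly", {
  map <- list(atom_tokens = list(1L, c(2L, 3L)), unmapped = integer(0))
  z <- rbind(c(1, 0), c(1, 0), c(0, 1))
  h <- aggregate_token_embeddings(map, z)
  expect_equal(h[1, ], c(1, 0))      # singleton: the embedding itself
  expect_equal(h[2, ], c(0.5, 0.5))  # uniform two-token average
  # softmax scores still sum to 1
  h2 <- aggregate_token_embeddings(map, z, scores = c(0, log(3), 0))
  expect_equal(sum(h2[2, ]), 1)
  expect_equal(h2[2, ], c(0.75, 0.25))
})

test_that("neighbour imputation resolves unmapped atoms iteratively", {
  mol <- parse_molecule("CCO")
  h <- rbind(c(1, 0), c(0, 1), c(0, 0))
  map <- list(atom_tokens = list(1L, 2L, integer(0)), unmapped = 3L)
  filled <- impute_unmapped(map, mol, h)
  expect_equal(filled[3, ], c(0, 1)) # mean of its single mapped neighbour

  # chain of two unmapped atoms resolves in two passes
  mol4 <- parse_molecule("CCCC")
  h4 <- rbind(c(2, 4), c(0, 0), c(0, 0), c(0, 0))
  map4 <- list(atom_tokens = list(1L, integer(0), integer(0), integer(0)),
               unmapped = 2:4)
  filled4 <- impute_unmapped(map4, mol4, h4)
  expect_equal(filled4[2, ], c(2, 4))
  expect_equal(filled4[4, ], c(2, 4))

  # unmapped isolated atom falls back to the zero vector
  salt <- parse_molecule("[Na+].[Cl-]")
  hs <- matrix(0, 2, 2)
  maps <- list(atom_tokens = list(integer(0), integer(0)), unmapped = 1:2)
  expect_equal(impute_unmapped(maps, salt, hs), matrix(0, 2, 2))
})

test_that("stub embeddings are deterministic across providers", {
  p1 <- embedding_provider()
  p2 <- embedding_provider()
  mol <- parse_molecule("OCC(O)c1ccccc1")
  e1 <- semantic_embeddings(mol, p1)
  e2 <- semantic_embeddings(mol, p2)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(10, 32))
  # unit-norm token vectors
  z <- p1$embed(c("C", "O"))
  expect_equal(rowSums(z^2), c(1, 1))
  expect_false(isTRUE(all.equal(z[1, ], z[2, ])))
})

test_that("fusion z-scores each modality and scales by modality weights", {
  set.seed(5)
  hb <- matrix(rnorm(40), 10, 4)
  ht <- cbind(matrix(rnorm(30), 10, 3), 7) # one constant column
  stats <- list(bert = fit_zscore(hb), trad = fit_zscore(ht))

  h0 <- fuse_features(hb, ht, stats, fusion_control())
  expect_equal(ncol(h0), 8)
  expect_equal(colMeans(h0), rep(0, 8), tolerance = 1e-12)
  expect_equal(apply(h0[, 1:7], 2, sd), rep(1, 7))
  expect_equal(h0[, 8], rep(0, 10)) # zero-variance column maps to 0

  # zero bert weight zeroes the semantic block
  h0_zero <- fuse_features(hb, ht, stats, fusion_control(w_bert = 0))
  expect_equal(h0_zero[, 1:4], matrix(0, 10, 4))

  # linearity: doubling w_trad doubles the traditional block exactly
  h0_double <- fuse_features(hb, ht, stats, fusion_control(w_trad = 2))
  expect_equal(h0_double[, 5:8], 2 * h0[, 5:8])

  # ablations drop a block entirely
  expect_equal(ncol(fuse_features(hb, ht, stats,
                                  fusion_control(modality = "traditional"))), 4)
  expect_equal(ncol(fuse_features(hb, ht, stats,
                                  fusion_control(modality = "bert"))), 4)
  expect_error(fuse_features(hb, ht, list(), fusion_control()), "not fitted")
})
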