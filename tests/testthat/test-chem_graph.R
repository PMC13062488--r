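test_that("parse_molecule populates per-atom attributes", {
  methane <- parse_molecule("C")
  expect_equal(nrow(methane$atoms), 1)
  expect_equal(methane$atoms$degree, 0)
  expect_equal(methane$atoms$num_h, 4)

  benzene <- parse_molecule("c1ccccc1")
  expect_equal(nrow(benzene$atoms), 6)
  expect_true(all(benzene$atoms$aromatic))
  expect_equal(nrow(benzene$bonds), 6)
  expect_true(all(benzene$bonds$order == "aromatic"))

  # spiro centre: shared by two rings, degree 4
  spiro <- parse_molecule("C1CC2(CC1)CCCC2")
  centre <- which(spiro$atoms$degree == 4)
  expect_length(centre, 1)
  expect_true(spiro$atoms$in_ring[centre])
  expect_true(all(vapply(spiro$rings, function(r) centre %in% r, TRUE)))
})

test_that("invalid SMILES raises a distinct error carrying the input", {
  err <- tryCatch(parse_molecule("not_a_smiles"), error = identity)
  expect_s3_class(err, "hypermol_invalid_smiles")
  expect_identical(err$smiles, "not_a_smiles")
  expect_error(parse_molecule(""), "non-empty")
})

test_that("functional-group matching emits one hyperedge per matched atom set", {
  ethanol <- parse_molecule("CCO")
  hydroxyl_only <- smarts_library()
  hydroxyl_only <- hydroxyl_only[hydroxyl_only$name == "hydroxyl", ]
  edges <- match_functional_groups(ethanol, hydroxyl_only)
  expect_length(edges, 1)
  expect_equal(edges[[1]]$members, 3L) # the oxygen
  expect_equal(edges[[1]]$annotations$name, "hydroxyl")

  expect_length(match_functional_groups(parse_molecule("CCCC")), 0)

  acetamide_edges <- match_functional_groups(parse_molecule("CC(=O)N"))
  expect_length(acetamide_edges, 1)
  expect_equal(acetamide_edges[[1]]$members, 2:4) # C, O, N of the amide
  expect_equal(acetamide_edges[[1]]$annotations$name, "amide")
})

test_that("ring systems yield SSSR rings plus fused-system hyperedges", {
  benzene_rings <- extract_ring_systems(parse_molecule("c1ccccc1"))
  expect_length(benzene_rings, 1)
  expect_equal(benzene_rings[[1]]$members, 1:6)
  expect_true(benzene_rings[[1]]$annotations$aromatic)
  expect_equal(benzene_rings[[1]]$annotations$ring_size, 6)

  naph <- extract_ring_systems(parse_molecule("c1ccc2ccccc2c1"))
  sizes <- vapply(naph, function(e) length(e$members), 0L)
  expect_equal(sort(sizes), c(6, 6, 10))
  fused <- naph[[which(sizes == 10)]]
  expect_equal(fused$annotations$kind, "fused_system")
  expect_true(fused$annotations$aromatic)

  expect_length(extract_ring_systems(parse_molecule("CCO")), 0)
})

test_that("special motifs: spiro, bridged and metal centres", {
  spiro <- extract_special_motifs(parse_molecule("C1CC2(CC1)CCCC2"))
  expect_length(spiro, 1)
  expect_equal(spiro[[1]]$annotations$kind, "spiro")
  expect_equal(spiro[[1]]$members, 1:9) # both rings, 9 atoms total

  expect_length(extract_special_motifs(parse_molecule("c1ccccc1")), 0)

  # norbornane: the two SSSR 5-rings share three atoms -> bridged
  nor <- extract_special_motifs(parse_molecule("C1CC2CCC1C2"))
  expect_length(nor, 1)
  expect_equal(nor[[1]]$annotations$kind, "bridged")

  salt <- extract_special_motifs(parse_molecule("[Na+].CC(=O)[O-]"))
  expect_length(salt, 1)
  expect_equal(salt[[1]]$annotations$kind, "metal_center")
  expect_equal(salt[[1]]$members, 1L) # lone ion: no bonded neighbours
})

test_that("ring connectivity links ring pairs and ring substituents", {
  biphenyl <- extract_ring_connectivity(parse_molecule("c1ccc(-c2ccccc2)cc1"))
  expect_length(biphenyl, 1)
  expect_length(biphenyl[[1]]$members, 12)
  expect_equal(biphenyl[[1]]$annotations$kind, "ring_pair")

  toluene <- extract_ring_connectivity(parse_molecule("Cc1ccccc1"))
  expect_length(toluene, 1)
  expect_length(toluene[[1]]$members, 7)
  expect_equal(toluene[[1]]$annotations$kind, "ring_substituent")

  expect_length(extract_ring_connectivity(parse_molecule("c1ccccc1")), 0)
})

test_that("isolated-atom coverage completes any partial hyperedge set", {
  methane <- parse_molecule("C")
  singles <- cover_isolated_atoms(methane, list())
  expect_length(singles, 1)
  expect_equal(singles[[1]]$members, 1L)
  expect_equal(singles[[1]]$annotations$kind, "singleton")

  butane <- parse_molecule("CCCC")
  edges <- cover_isolated_atoms(butane, list())
  expect_length(edges, 4)
  expect_equal(edges[[2]]$members, 1:3) # atom 2 plus both neighbours

  benzene <- parse_molecule("c1ccccc1")
  ring <- extract_ring_systems(benzene)
  expect_length(cover_isolated_atoms(benzene, ring), 0)
})

test_that("build_hypergraph matches the hand-derived toy suite", {
  for (case in toy_suite()) {
    hg <- build_hypergraph(case$smiles)
    expect_equal(nrow(hg$mol$atoms), case$expect$n_atoms, info = case$name)
    cats <- vapply(hg$hyperedges, `[[`, "", "category")
    for (cat in c("functional_group", "ring", "special_motif",
                  "ring_connectivity", "isolated")) {
      expect_equal(sum(cats == cat), case$expect[[cat]],
                   info = paste(case$name, cat))
    }
    for (cat in names(case$expect$member_sets)) {
      got <- lapply(hg$hyperedges[cats == cat], `[[`, "members")
      for (want in case$expect$member_sets[[cat]]) {
        expect_true(any(vapply(got, function(g) identical(g, as.integer(want)), TRUE)),
                    info = paste(case$name, cat))
      }
    }
    # coverage invariant
    expect_true(all(Matrix::rowSums(hg$incidence) >= 1), info = case$name)
  }
})

test_that("hypergraph construction is deterministic and coverage always holds", {
  smiles <- property_molecules(n = 60, seed = 21)
  for (s in smiles[1:25]) {
    hg1 <- build_hypergraph(parse_molecules(s, cache = FALSE)[[1]])
    hg2 <- build_hypergraph(parse_molecules(s, cache = FALSE)[[1]])
    expect_identical(lapply(hg1$hyperedges, `[`, c("category", "members")),
                     lapply(hg2$hyperedges, `[`, c("category", "members")),
                     info = s)
    expect_true(all(Matrix::rowSums(hg1$incidence) >= 1), info = s)
  }
})

test_that("disabling hyperedge classes never increases M and keeps coverage", {
  smiles <- c("Cc1ccccc1", "CC(=O)N", "C1CC2(CC1)CCCC2", "OCC(O)c1ccncc1")
  full_cfg <- hypergraph_control()
  for (s in smiles) {
    full <- build_hypergraph(s, full_cfg)
    for (drop in c("functional_groups", "rings", "special_motifs",
                   "ring_connectivity")) {
      args <- list(TRUE, TRUE, TRUE, TRUE)
      names(args) <- c("functional_groups", "rings", "special_motifs",
                       "ring_connectivity")
      args[[drop]] <- FALSE
      hg <- build_hypergraph(s, do.call(hypergraph_control, args))
      n_structural <- function(h) {
        sum(vapply(h$hyperedges, `[[`, "", "category") != "isolated")
      }
      expect_lte(n_structural(hg), n_structural(full))
      expect_true(all(Matrix::rowSums(hg$incidence) >= 1))
    }
  }
})

test_that("two-atom functional-group matches are valid hyperedges", {
  # C-O of an ether: a pairwise connection encoded as a 2-atom hyperedge
  edges <- match_functional_groups(parse_molecule("COC"))
  sizes <- vapply(edges, function(e) length(e$members), 0L)
  expect_true(any(sizes == 2))
  for (e in edges[sizes == 2]) {
    expect_length(unique(e$members), 2)
  }
})

test_that("hypergraph JSON export uses 0-based indices and round-trips", {
  hg <- build_hypergraph("CC(=O)N")
  json <- hypergraph_json(hg)
  parsed <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  expect_equal(parsed$num_atoms, 4)
  members <- unlist(lapply(parsed$hyperedges, `[[`, "members"))
  expect_true(min(members) == 0)
  expect_equal(length(parsed$hyperedges), length(hg$hyperedges))
})
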