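# Synthetic fixtures: toy molecules with hand-derived hypergraph structure,
# labelled datasets generated from a small fragment grammar (guaranteed
# valid SMILES with known substructure counts), and random hypergraph-shaped
# instances for numerical oracle tests.

#' Hand-derived toy molecule suite
#'
#' Eleven molecules spanning all five hyperedge categories, each with its
#' expected atom count and per-category hyperedge counts derived by hand
#' (SSSR enumeration and pattern application on paper).
#'
#' @return A list of cases, each with `name`, `smiles` and an `expect` list
#'   (`n_atoms` and per-category hyperedge counts; some cases also pin
#'   specific member sets).
#' @export
toy_suite <- function() {
  case <- function(name, smiles, n_atoms, fg = 0, ring = 0, special = 0,
                   conn = 0, isolated = 0, member_sets = NULL) {
    list(name = name, smiles = smiles,
         expect = list(n_atoms = n_atoms, functional_group = fg, ring = ring,
                       special_motif = special, ring_connectivity = conn,
                       isolated = isolated, member_sets = member_sets))
  }
  list(
    case("methane", "C", 1, isolated = 1, member_sets = list(isolated = list(1L))),
    case("ethanol", "CCO", 3, fg = 2, isolated = 1,
         member_sets = list(functional_group = list(3L, c(2L, 3L)))),
    case("butane", "CCCC", 4, isolated = 4),
    case("benzene", "c1ccccc1", 6, ring = 1,
         member_sets = list(ring = list(1:6))),
    case("toluene", "Cc1ccccc1", 7, ring = 1, conn = 1,
         member_sets = list(ring_connectivity = list(1:7))),
    case("acetamide", "CC(=O)N", 4, fg = 1, isolated = 1,
         member_sets = list(functional_group = list(2:4))),
    case("naphthalene", "c1ccc2ccccc2c1", 10, ring = 3, conn = 1),
    case("biphenyl", "c1ccc(-c2ccccc2)cc1", 12, ring = 2, conn = 1,
         member_sets = list(ring_connectivity = list(1:12))),
    # two five-membered rings sharing one atom (spiro[4.4]nonane)
    case("spirononane", "C1CC2(CC1)CCCC2", 9, ring = 3, special = 1, conn = 1,
         member_sets = list(special_motif = list(1:9))),
    # bicyclo[2.2.1]heptane: SSSR rings share three atoms -> bridged
    case("norbornane", "C1CC2CCC1C2", 7, ring = 3, special = 1, conn = 1,
         member_sets = list(special_motif = list(1:7))),
    case("sodium_acetate", "[Na+].CC(=O)[O-]", 5, fg = 1, special = 1,
         isolated = 1, member_sets = list(special_motif = list(1L)))
  )
}

# Fragment grammar: a 3-7 carbon backbone whose carbons carry optional
# substituents. Composition by string assembly keeps every molecule valid
# and its motif counts known by construction.
grammar_molecule <- function(len, oh_carbons, substituents) {
  branches <- vector("list", len)
  for (c in oh_carbons) branches[[c]] <- c(branches[[c]], "O")
  for (i in seq_along(substituents$pos)) {
    p <- substituents$pos[i]
    branches[[p]] <- c(branches[[p]], substituents$frag[i])
  }
  paste(vapply(seq_len(len), function(i) {
    paste0("C", paste0(vapply(branches[[i]], function(b) paste0("(", b, ")"), ""),
                       collapse = ""))
  }, ""), collapse = "")
}

# Ring substituents are drawn from several ring systems so the generated
# set spans many Bemis-Murcko scaffold groups and scaffold splitting yields
# non-trivial train/valid/test partitions.
GRAMMAR_RINGS <- c("c1ccccc1", "c1cccnc1", "C1CCCCC1", "c1ccsc1", "C1CCCC1")

sample_substituents <- function(len, taken, frags, p_any = 0.35, p_ring = 0.4,
                                max_extra = 2L) {
  pos <- integer(0); frag <- character(0)
  free <- setdiff(seq_len(len), taken)
  for (p in free) {
    if (length(pos) >= max_extra) break
    if (stats::runif(1) < p_any) {
      pos <- c(pos, p)
      frag <- c(frag, if (stats::runif(1) < p_ring) {
        sample(GRAMMAR_RINGS, 1)
      } else {
        sample(frags, 1)
      })
    }
  }
  list(pos = pos, frag = frag)
}

#' Generate a synthetic hydroxyl-count regression dataset
#'
#' Molecules are assembled from a fragment grammar (alkyl backbone with
#' hydroxyl, methyl, amine and phenyl substituents); the label is the
#' number of hydroxyl groups plus Gaussian noise. Phenyl substituents give
#' the set several distinct Bemis-Murcko scaffolds so scaffold splitting
#' produces non-trivial partitions.
#'
#' @param n Number of molecules.
#' @param noise_sd Label noise standard deviation (>= 0).
#' @param seed Integer seed; the output is byte-identical for a fixed seed.
#' @param path Optional CSV output path (columns `smiles`, `y`).
#' @return data.frame with `smiles`, `y` and the noiseless `n_hydroxyl`.
#' @export
simulate_regression <- function(n = 2000L, noise_sd = 0.1, seed = 1L,
                                path = NULL) {
  stopifnot(noise_sd >= 0)
  df <- with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      len <- sample(3:7, 1)
      n_oh <- sample(0:3, 1)
      oh_carbons <- sort(sample(seq_len(len), n_oh))
      subs <- sample_substituents(len, oh_carbons, frags = c("C", "N"))
      list(smiles = grammar_molecule(len, oh_carbons, subs), n_oh = n_oh)
    })
    data.frame(
      smiles = vapply(rows, `[[`, "", "smiles"),
      y = vapply(rows, `[[`, 0L, "n_oh") + stats::rnorm(n, 0, noise_sd),
      n_hydroxyl = vapply(rows, `[[`, 0L, "n_oh"),
      stringsAsFactors = FALSE
    )
  })
  if (!is.null(path)) utils::write.csv(df[c("smiles", "y")], path, row.names = FALSE)
  df
}

#' Generate a synthetic amide-presence classification dataset
#'
#' Balanced binary data: positives carry one or two carboxamide
#' substituents, negatives none (and no other carbonyl, so no amide pattern
#' can arise); both classes share the same backbone and decoy-substituent
#' distribution (hydroxyl, methyl, amine, phenyl, fluoride).
#'
#' @param n Total number of molecules (positives and negatives are n/2
#'   each).
#' @param seed Integer seed.
#' @param path Optional CSV output path.
#' @return data.frame with `smiles`, `y` (1 = contains an amide) in seeded
#'   shuffled order.
#' @export
simulate_classification <- function(n = 2000L, seed = 1L, path = NULL) {
  stopifnot(n %% 2 == 0)
  df <- with_seed(seed, {
    gen <- function(positive) {
      len <- sample(3:7, 1)
      amide_carbons <- if (positive) {
        sort(sample(seq_len(len), sample(1:2, 1)))
      } else integer(0)
      subs <- sample_substituents(len, amide_carbons,
                                  frags = c("C", "N", "O", "F"), p_any = 0.4)
      subs$pos <- c(subs$pos, amide_carbons)
      subs$frag <- c(subs$frag, rep("C(=O)N", length(amide_carbons)))
      grammar_molecule(len, integer(0), subs)
    }
    out <- data.frame(
      smiles = c(vapply(seq_len(n / 2), function(i) gen(TRUE), ""),
                 vapply(seq_len(n / 2), function(i) gen(FALSE), "")),
      y = rep(c(1L, 0L), each = n / 2),
      stringsAsFactors = FALSE
    )
    out[sample.int(n), , drop = FALSE]
  })
  rownames(df) <- NULL
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}

#' Random hypergraph-shaped instance
#'
#' Random memberships with guaranteed full atom coverage plus random node
#' and hyperedge features - the workhorse of the dense-oracle equivalence
#' and attention-normalisation tests.
#'
#' @param n_nodes,n_edges Numbers of nodes and hyperedges (>= 1).
#' @param input_dim Node feature width.
#' @param seed Integer seed.
#' @return List with `h0` (nodes x input_dim), `fe` (edges x 5) and
#'   `members` (list of member index vectors).
#' @export
random_hypergraph <- function(n_nodes, n_edges, input_dim = 8L, seed = 1L) {
  stopifnot(n_nodes >= 1, n_edges >= 1)
  with_seed(seed, {
    members <- lapply(seq_len(n_edges), function(j) {
      sort(sample.int(n_nodes, sample.int(n_nodes, 1)))
    })
    uncovered <- setdiff(seq_len(n_nodes), unique(unlist(members)))
    if (length(uncovered)) {
      members[[n_edges]] <- sort(union(members[[n_edges]], uncovered))
    }
    list(
      h0 = matrix(stats::rnorm(n_nodes * input_dim), n_nodes, input_dim),
      fe = matrix(stats::runif(n_edges * 5), n_edges, 5),
      members = members
    )
  })
}
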