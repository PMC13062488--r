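# Molecular hypergraph construction. Atoms are nodes; hyperedges are
# chemically meaningful substructures drawn from five classes:
# functional_group, ring, special_motif, ring_connectivity, isolated.
# A final coverage pass guarantees every atom lies in at least one hyperedge.

HYPEREDGE_CATEGORIES <- c(
  "functional_group", "ring", "special_motif", "ring_connectivity", "isolated"
)

new_hyperedge <- function(category, members, annotations = list()) {
  stopifnot(category %in% HYPEREDGE_CATEGORIES, length(members) >= 1)
  list(
    id = NA_integer_,
    category = category,
    members = sort(unique(as.integer(members))),
    annotations = annotations
  )
}

adjacency_list <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (i in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[i]; b <- mol$bonds$a2[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, function(v) sort(unique(v)))
}

#' Hypergraph construction options
#'
#' Each hyperedge class can be toggled independently (the isolated-atom
#' coverage pass always runs last and cannot be disabled, so atom coverage
#' survives any ablation).
#'
#' @param functional_groups,rings,special_motifs,ring_connectivity Logical
#'   switches for the corresponding hyperedge classes.
#' @return A list of class `hypergraph_control`.
#' @export
hypergraph_control <- function(functional_groups = TRUE, rings = TRUE,
                               special_motifs = TRUE, ring_connectivity = TRUE) {
  structure(
    list(
      functional_groups = isTRUE(functional_groups),
      rings = isTRUE(rings),
      special_motifs = isTRUE(special_motifs),
      ring_connectivity = isTRUE(ring_connectivity)
    ),
    class = "hypergraph_control"
  )
}

#' Functional-group hyperedges from SMARTS matching
#'
#' One hyperedge per distinct matched atom set per pattern; overlapping
#' matches are retained so atoms may participate in several functional-group
#' hyperedges. Ordering is deterministic: library order, then smallest
#' member index.
#'
#' @param mol An `hmol` molecule.
#' @param library A `smarts_library`; defaults to the matches already stored
#'   on the molecule (computed with the bundled 69-pattern library).
#' @return List of hyperedges of category `functional_group`.
#' @export
match_functional_groups <- function(mol, library = NULL) {
  stored <- mol$matches$fg
  if (!is.null(library)) {
    if (!all(library$name %in% names(stored))) {
      mol <- parse_molecule(mol$smiles, fg_library = library)
      stored <- mol$matches$fg
    }
    stored <- stored[library$name]
  }
  edges <- list()
  for (pattern in names(stored)) {
    for (members in stored[[pattern]]) {
      edges[[length(edges) + 1L]] <- new_hyperedge(
        "functional_group", members, list(name = pattern)
      )
    }
  }
  edges
}

#' Ring-system hyperedges
#'
#' One hyperedge per SSSR ring (annotated with ring size and aromaticity),
#' plus one hyperedge per fused polycyclic system (the union of SSSR rings
#' sharing at least one atom) whenever that system contains two or more
#' rings.
#'
#' @param mol An `hmol` molecule.
#' @return List of hyperedges of category `ring`.
#' @export
extract_ring_systems <- function(mol) {
  rings <- mol$rings
  edges <- lapply(rings, function(r) {
    new_hyperedge("ring", r, list(
      ring_size = length(r),
      aromatic = all(mol$atoms$aromatic[r])
    ))
  })
  if (length(rings) >= 2) {
    # union-find over rings sharing >= 1 atom
    parent <- seq_along(rings)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_along(rings)) for (j in seq_len(i - 1)) {
      if (length(intersect(rings[[i]], rings[[j]]))) {
        parent[find(i)] <- find(j)
      }
    }
    roots <- vapply(seq_along(rings), find, 0L)
    for (root in sort(unique(roots))) {
      cluster <- which(roots == root)
      if (length(cluster) >= 2) {
        members <- sort(unique(unlist(rings[cluster])))
        edges[[length(edges) + 1L]] <- new_hyperedge("ring", members, list(
          kind = "fused_system",
          n_rings = length(cluster),
          aromatic = all(mol$atoms$aromatic[members])
        ))
      }
    }
  }
  edges
}

#' Special structural motif hyperedges
#'
#' Metal coordination centers (a metallic atom plus its bonded neighbours),
#' spirocyclic systems (union of two SSSR rings sharing exactly one atom)
#' and bridged ring systems (union of two SSSR rings sharing three or more
#' atoms). Rings sharing exactly two atoms are ordinary fusions and are
#' handled by the fused-system ring hyperedge instead.
#'
#' @param mol An `hmol` molecule.
#' @return List of hyperedges of category `special_motif`.
#' @export
extract_special_motifs <- function(mol) {
  edges <- list()
  metals <- metal_elements()
  adj <- adjacency_list(mol)
  for (v in which(mol$atoms$symbol %in% metals)) {
    edges[[length(edges) + 1L]] <- new_hyperedge(
      "special_motif", c(v, adj[[v]]),
      list(kind = "metal_center", metal = mol$atoms$symbol[v])
    )
  }
  rings <- mol$rings
  if (length(rings) >= 2) {
    for (i in seq_along(rings)) for (j in seq_len(i - 1)) {
      shared <- length(intersect(rings[[i]], rings[[j]]))
      kind <- if (shared == 1) "spiro" else if (shared >= 3) "bridged" else NULL
      if (!is.null(kind)) {
        edges[[length(edges) + 1L]] <- new_hyperedge(
          "special_motif", union(rings[[i]], rings[[j]]), list(kind = kind)
        )
      }
    }
  }
  edges
}

#' Ring-connectivity hyperedges
#'
#' (a) For every pair of SSSR rings joined by a direct bond between their
#' members or sharing at least one atom, one hyperedge spanning the union of
#' both rings. (b) For every ring with at least one substituent (a non-ring
#' atom directly bonded to a ring member), one hyperedge spanning the ring
#' plus its first-shell substituent atoms.
#'
#' @param mol An `hmol` molecule.
#' @param rings List of this molecule's single-ring hyperedges (defaults to
#'   the SSSR rings stored on the molecule).
#' @return List of hyperedges of category `ring_connectivity`.
#' @export
extract_ring_connectivity <- function(mol, rings = NULL) {
  ring_sets <- if (is.null(rings)) mol$rings else lapply(rings, `[[`, "members")
  edges <- list()
  if (length(ring_sets) == 0) return(edges)
  bonded <- function(set_a, set_b) {
    any((mol$bonds$a1 %in% set_a & mol$bonds$a2 %in% set_b) |
        (mol$bonds$a1 %in% set_b & mol$bonds$a2 %in% set_a))
  }
  if (length(ring_sets) >= 2) {
    for (i in seq_along(ring_sets)) for (j in seq_len(i - 1)) {
      shares <- length(intersect(ring_sets[[i]], ring_sets[[j]])) > 0
      if (shares || bonded(ring_sets[[i]], ring_sets[[j]])) {
        edges[[length(edges) + 1L]] <- new_hyperedge(
          "ring_connectivity", union(ring_sets[[i]], ring_sets[[j]]),
          list(kind = "ring_pair")
        )
      }
    }
  }
  in_any_ring <- mol$atoms$in_ring
  adj <- adjacency_list(mol)
  for (r in ring_sets) {
    subs <- setdiff(unlist(adj[r]), r)
    subs <- subs[!in_any_ring[subs]]
    if (length(subs)) {
      edges[[length(edges) + 1L]] <- new_hyperedge(
        "ring_connectivity", c(r, subs), list(kind = "ring_substituent")
      )
    }
  }
  edges
}

#' Isolated-atom coverage hyperedges
#'
#' For every atom not yet covered by any hyperedge, emit one hyperedge
#' containing the atom and its directly bonded neighbours (or the atom alone
#' if it has none). After this pass atom coverage is complete by
#' construction.
#'
#' @param mol An `hmol` molecule.
#' @param existing List of hyperedges built so far.
#' @return List of hyperedges of category `isolated`.
#' @export
cover_isolated_atoms <- function(mol, existing) {
  covered <- rep(FALSE, nrow(mol$atoms))
  for (e in existing) covered[e$members] <- TRUE
  adj <- adjacency_list(mol)
  edges <- list()
  for (v in which(!covered)) {
    nbrs <- adj[[v]]
    edges[[length(edges) + 1L]] <- new_hyperedge(
      "isolated", c(v, nbrs),
      list(kind = if (length(nbrs)) "neighborhood" else "singleton", center = v)
    )
  }
  edges
}

dedupe_hyperedges <- function(edges) {
  if (!length(edges)) return(edges)
  keys <- vapply(edges, function(e) {
    paste(e$category, paste(e$members, collapse = ","))
  }, "")
  edges[!duplicated(keys)]
}

#' Build the molecular hypergraph for one molecule
#'
#' Runs the full construction pipeline: SMILES parsing, functional-group
#' SMARTS matching, ring systems, special motifs, ring connectivity, and the
#' always-on isolated-atom coverage pass. Hyperedges identical in
#' (member set, category) are collapsed; identical member sets in different
#' categories are both kept. The result is deterministic for a given SMILES.
#'
#' @param smiles A SMILES string, or an already-parsed `hmol` object.
#' @param control A [hypergraph_control()] toggling hyperedge classes.
#' @param fg_library Optional custom functional-group library.
#' @return An object of class `hmol_hypergraph` with fields `mol`,
#'   `hyperedges` and `incidence` (sparse N x M logical matrix).
#' @examples
#' \dontrun{
#' hg <- build_hypergraph("CC(=O)N")
#' print(hg)
#' }
#' @export
build_hypergraph <- function(smiles, control = hypergraph_control(),
                             fg_library = NULL) {
  mol <- if (inherits(smiles, "hmol")) smiles else parse_molecule(smiles)
  edges <- list()
  if (control$functional_groups) {
    edges <- c(edges, match_functional_groups(mol, fg_library))
  }
  ring_edges <- if (control$rings) extract_ring_systems(mol) else list()
  edges <- c(edges, ring_edges)
  if (control$special_motifs) edges <- c(edges, extract_special_motifs(mol))
  if (control$ring_connectivity) edges <- c(edges, extract_ring_connectivity(mol))
  edges <- dedupe_hyperedges(edges)
  edges <- c(edges, cover_isolated_atoms(mol, edges))
  for (i in seq_along(edges)) edges[[i]]$id <- i
  n <- nrow(mol$atoms); m <- length(edges)
  iv <- unlist(lapply(edges, `[[`, "members"))
  ie <- rep(seq_len(m), vapply(edges, function(e) length(e$members), 0L))
  incidence <- Matrix::sparseMatrix(i = iv, j = ie, x = TRUE, dims = c(n, m))
  hg <- structure(
    list(mol = mol, hyperedges = edges, incidence = incidence),
    class = "hmol_hypergraph"
  )
  stopifnot(all(Matrix::rowSums(incidence) >= 1)) # complete atomic coverage
  hg
}

#' @export
print.hmol_hypergraph <- function(x, ...) {
  cats <- vapply(x$hyperedges, `[[`, "", "category")
  cat("<molecular hypergraph> ", x$mol$smiles, "\n", sep = "")
  cat("  N = ", nrow(x$mol$atoms), " atoms, M = ", length(x$hyperedges),
      " hyperedges\n", sep = "")
  print(table(factor(cats, levels = HYPEREDGE_CATEGORIES)))
  invisible(x)
}

#' @export
as.data.frame.hmol_hypergraph <- function(x, ...) {
  data.frame(
    id = vapply(x$hyperedges, `[[`, 0L, "id"),
    category = vapply(x$hyperedges, `[[`, "", "category"),
    size = vapply(x$hyperedges, function(e) length(e$members), 0L),
    members = vapply(x$hyperedges, function(e) paste(e$members, collapse = ","), ""),
    annotation = vapply(x$hyperedges, function(e) {
      paste(unlist(e$annotations), collapse = ";")
    }, ""),
    stringsAsFactors = FALSE
  )
}

#' Export a hypergraph as JSON
#'
#' Atom indices in the export are 0-based, matching the external interface
#' used by the command-line tool and the test fixtures.
#'
#' @param hg An `hmol_hypergraph`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
hypergraph_json <- function(hg, path = NULL) {
  payload <- list(
    smiles = hg$mol$smiles,
    num_atoms = nrow(hg$mol$atoms),
    hyperedges = lapply(hg$hyperedges, function(e) {
      list(
        id = e$id, category = e$category,
        members = as.integer(e$members) - 1L,
        annotations = e$annotations
      )
    })
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
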