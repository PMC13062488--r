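# Every hyperedge is encoded as a 5-dimensional feature vector in fixed
# order: [type_code, size_norm, electronegativity, centrality,
# pharmacophore_flag]. All five components share a comparable [0, 1] scale.

HYPEREDGE_FEATURE_NAMES <- c(
  "type_code", "size_norm", "electronegativity", "centrality", "pharmacophore_flag"
)

# Substructure sizes are normalised by a typical maximum of 20 atoms and
# capped at 1; Pauling electronegativities are scaled by 1/4 (max 3.98).
SIZE_NORMALIZER <- 20
EN_SCALE <- 4

#' Chemical-type code of a hyperedge
#'
#' Encodes the substructure category as a scalar in \[0, 1\] over the fixed
#' category ordering (functional_group, ring, special_motif,
#' ring_connectivity, isolated).
#'
#' @param e A hyperedge.
#' @return Numeric scalar in \[0, 1\].
#' @export
chemical_type_code <- function(e) {
  idx <- match(e$category, HYPEREDGE_CATEGORIES)
  if (is.na(idx)) stop("unknown hyperedge category: ", e$category)
  (idx - 1) / (length(HYPEREDGE_CATEGORIES) - 1)
}

#' Normalised substructure size
#'
#' `min(|e| / 20, 1)` - a proxy for steric bulk.
#'
#' @param e A hyperedge.
#' @return Numeric scalar in (0, 1\].
#' @export
normalized_size <- function(e) {
  min(length(e$members) / SIZE_NORMALIZER, 1)
}

#' Electronic character of a hyperedge
#'
#' The mean Pauling electronegativity of the member atoms (uniform weights),
#' scaled by 1/4 to lie near \[0, 1\]. A member element missing from the
#' table is an error, never a silent default.
#'
#' @param e A hyperedge.
#' @param mol The parent `hmol` molecule.
#' @param table Named electronegativity vector, see
#'   [electronegativity_table()].
#' @param weights Optional per-member weights (default uniform).
#' @return Numeric scalar.
#' @export
electronic_feature <- function(e, mol, table = electronegativity_table(),
                               weights = NULL) {
  symbols <- mol$atoms$symbol[e$members]
  missing <- setdiff(symbols, names(table))
  if (length(missing)) {
    stop("no electronegativity entry for element(s): ",
         paste(missing, collapse = ", "))
  }
  en <- table[symbols]
  if (is.null(weights)) weights <- rep(1, length(en))
  stats::weighted.mean(en, weights) / EN_SCALE
}

#' Topological centrality of a hyperedge
#'
#' The fraction of the other hyperedges that share at least one atom with
#' `e`; 0 when the hypergraph has a single hyperedge. Highlights core
#' scaffolds that touch many substructures.
#'
#' @param e A hyperedge.
#' @param hg The parent `hmol_hypergraph`.
#' @return Numeric scalar in \[0, 1\].
#' @export
topological_centrality <- function(e, hg) {
  m <- length(hg$hyperedges)
  if (m <= 1) return(0)
  overlaps <- vapply(hg$hyperedges, function(other) {
    other$id != e$id && length(intersect(other$members, e$members)) > 0
  }, TRUE)
  sum(overlaps) / (m - 1)
}

#' Pharmacophore match indicator
#'
#' 1 iff some pharmacophore pattern match in the molecule has all of its
#' matched atoms inside the hyperedge's member set.
#'
#' @param e A hyperedge.
#' @param mol The parent `hmol` molecule (carries the stored pharmacophore
#'   matches computed with the bundled six-class library).
#' @return 0 or 1.
#' @export
pharmacophore_match <- function(e, mol) {
  for (per_pattern in mol$matches$ph) {
    for (m in per_pattern) {
      if (all(m %in% e$members)) return(1)
    }
  }
  0
}

#' Featurize one hyperedge
#'
#' @param e A hyperedge.
#' @param mol The parent molecule.
#' @param hg The parent hypergraph.
#' @param table Electronegativity table.
#' @return Named numeric vector of length 5.
#' @export
featurize_hyperedge <- function(e, mol, hg, table = electronegativity_table()) {
  stats::setNames(
    c(
      chemical_type_code(e),
      normalized_size(e),
      electronic_feature(e, mol, table),
      topological_centrality(e, hg),
      pharmacophore_match(e, mol)
    ),
    HYPEREDGE_FEATURE_NAMES
  )
}

#' Feature matrix for all hyperedges of a hypergraph
#'
#' @param hg An `hmol_hypergraph`.
#' @param table Electronegativity table.
#' @return Numeric matrix, one row per hyperedge, 5 columns.
#' @export
hyperedge_features <- function(hg, table = electronegativity_table()) {
  out <- t(vapply(
    hg$hyperedges,
    function(e) featurize_hyperedge(e, hg$mol, hg, table),
    numeric(length(HYPEREDGE_FEATURE_NAMES))
  ))
  colnames(out) <- HYPEREDGE_FEATURE_NAMES
  out
}
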