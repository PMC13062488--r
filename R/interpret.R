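# Attention-based interpretability: averaged attention coefficients turn
# into hyperedge importance scores, which propagate to per-atom relevance.

#' Average attention coefficients over heads
#'
#' @param record Attention record from a recorded forward pass: a list with
#'   `alpha` (per-layer matrices, one column per head, one row per
#'   node-hyperedge incidence), `iv` and `ie` incidence indices.
#' @param layer Layer index.
#' @return Numeric vector of head-averaged coefficients, one per incidence;
#'   per-hyperedge sums remain 1.
#' @export
average_heads <- function(record, layer) {
  if (layer < 1 || layer > length(record$alpha)) {
    stop("layer out of range: ", layer)
  }
  rowMeans(record$alpha[[layer]])
}

#' Hyperedge importance scores
#'
#' The importance of a hyperedge is the mean head-averaged attention of its
#' member atoms at the final propagation layer: substructures whose atoms
#' receive concentrated attention score high.
#'
#' @param hg The `hmol_hypergraph`.
#' @param abar Head-averaged attention from [average_heads()] (final layer).
#' @param record The attention record (for the incidence indices).
#' @return Numeric vector `I_e`, one score in (0, 1\] per hyperedge.
#' @export
hyperedge_importance <- function(hg, abar, record) {
  sums <- as.numeric(rowsum(abar, record$ie))
  sizes <- vapply(hg$hyperedges, function(e) length(e$members), 0L)
  sums / sizes
}

#' Per-atom relevance scores
#'
#' Each atom's raw relevance is the sum over its incident hyperedges of the
#' hyperedge importance weighted by the atom's own averaged attention in
#' that hyperedge; scores are then min-max normalised to \[0, 1\] per
#' molecule (an all-constant vector maps to all ones).
#'
#' @param hg The `hmol_hypergraph`.
#' @param importance Hyperedge importances `I_e`.
#' @param abar Head-averaged final-layer attention.
#' @param record The attention record.
#' @return Numeric vector of per-atom scores in \[0, 1\].
#' @export
atom_importance <- function(hg, importance, abar, record) {
  raw <- as.numeric(rowsum(abar * importance[record$ie], record$iv))
  rng <- range(raw)
  if (diff(rng) < 1e-12) return(rep(1, length(raw)))
  (raw - rng[1]) / diff(rng)
}

#' Explain a prediction via attention importances
#'
#' Runs a recorded forward pass for one molecule and derives hyperedge and
#' atom importance scores from the final-layer attention.
#'
#' @param object A fitted `hypermol` model.
#' @param smiles A single SMILES string.
#' @param layer Layer whose attention feeds the scores (default: the final
#'   layer).
#' @param ... Unused.
#' @return An object of class `hypermol_explanation`: prediction, ranked
#'   hyperedge table and per-atom scores.
#' @export
explain <- function(object, ...) UseMethod("explain")

#' @rdname explain
#' @export
explain.hypermol <- function(object, smiles, layer = NULL, ...) {
  mol <- parse_molecule(smiles)
  feats <- featurize_molecules(list(mol), object$graph,
                               rebuild_provider(object),
                               electronegativity_table())
  h0 <- fuse_all(feats, object$stats, object$fusion)
  b <- hgat_batch(h0, feats$fe, feats$members)
  fwd <- hgat_forward(object$params, b, object$control, record = TRUE)
  if (is.null(layer)) layer <- object$control$layers
  record <- list(alpha = fwd$attention, iv = b$iv, ie = b$ie)
  hg <- feats$graphs[[1]]
  abar <- average_heads(record, layer)
  imp <- hyperedge_importance(hg, abar, record)
  atom <- atom_importance(hg, imp, abar, record)
  pred <- fwd$pred[1, ]
  if (object$task == "classification") pred <- 1 / (1 + exp(-pred))
  edges <- as.data.frame(hg)
  edges$importance <- imp
  edges <- edges[order(-edges$importance, edges$id), ]
  structure(list(
    smiles = smiles,
    prediction = stats::setNames(pred, object$task_names),
    hypergraph = hg,
    hyperedges = edges,
    atom_scores = atom,
    layer = layer
  ), class = "hypermol_explanation")
}

#' @export
print.hypermol_explanation <- function(x, n = 5, ...) {
  cat("<explanation> ", x$smiles, "\n", sep = "")
  cat("  prediction:", paste(sprintf("%s = %.4f", names(x$prediction),
                                     x$prediction), collapse = ", "), "\n")
  cat("  top hyperedges (layer ", x$layer, "):\n", sep = "")
  print(utils::head(x$hyperedges[c("id", "category", "members", "annotation",
                                   "importance")], n), row.names = FALSE)
  invisible(x)
}

#' Export an explanation as heatmap-ready JSON
#'
#' Atom indices in the export are 0-based, matching the hypergraph export.
#'
#' @param x A `hypermol_explanation`.
#' @param path Optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
explanation_json <- function(x, path = NULL) {
  payload <- list(
    smiles = x$smiles,
    prediction = as.list(x$prediction),
    atom_scores = x$atom_scores,
    hyperedge_scores = lapply(seq_len(nrow(x$hyperedges)), function(i) {
      e <- x$hyperedges[i, ]
      members <- as.integer(strsplit(e$members, ",")[[1]]) - 1L
      list(id = e$id, category = e$category, members = members,
           annotation = e$annotation, importance = e$importance)
    })
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Plot atom and hyperedge importances
#'
#' @param x A `hypermol_explanation`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.hypermol_explanation <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::barplot(x$atom_scores, names.arg = seq_along(x$atom_scores),
                    xlab = "atom", ylab = "relevance", main = x$smiles, ...)
  top <- utils::head(x$hyperedges, 8)
  graphics::barplot(top$importance,
                    names.arg = paste0(top$id, ":", substr(top$category, 1, 4)),
                    las = 2, ylab = "hyperedge importance", ...)
  invisible(x)
}
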