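# Multimodal atom features: classical physicochemical descriptors fused with
# token-level chemical-language embeddings projected onto atoms.

TRADITIONAL_DESCRIPTOR_NAMES <- c(
  "z_norm", "degree_norm", "formal_charge_norm", "aromatic", "radical_electrons",
  "gasteiger_charge", "ring_flag", "h_norm",
  "bond_single", "bond_double", "bond_triple", "bond_aromatic",
  "mw_norm", "logp_norm", "tpsa_norm"
)

#' Traditional per-atom physicochemical descriptors
#'
#' Fixed-order concatenation per atom: normalised atomic number Z/100,
#' degree/4, formal charge/8, aromaticity flag, radical-electron count,
#' Gasteiger partial charge, ring-membership flag, attached-H count/4, the
#' normalised histogram of incident bond types over
#' \{single, double, triple, aromatic\} (summing to 1, or all zero for
#' isolated atoms), and the molecule-level triplet MW/500, logP/10,
#' TPSA/100 repeated on every atom. Non-finite partial charges are replaced
#' by 0 at parse time.
#'
#' @param mol An `hmol` molecule.
#' @return Numeric matrix with one row per atom and 15 named columns.
#' @export
traditional_descriptors <- function(mol) {
  a <- mol$atoms
  n <- nrow(a)
  hist <- matrix(0, n, 4,
                 dimnames = list(NULL, c("single", "double", "triple", "aromatic")))
  if (nrow(mol$bonds)) {
    for (i in seq_len(nrow(mol$bonds))) {
      ord <- mol$bonds$order[i]
      hist[mol$bonds$a1[i], ord] <- hist[mol$bonds$a1[i], ord] + 1
      hist[mol$bonds$a2[i], ord] <- hist[mol$bonds$a2[i], ord] + 1
    }
    tot <- rowSums(hist)
    nz <- tot > 0
    hist[nz, ] <- hist[nz, , drop = FALSE] / tot[nz]
  }
  out <- cbind(
    a$z / 100, a$degree / 4, a$formal_charge / 8, as.numeric(a$aromatic),
    a$radicals, a$gasteiger, as.numeric(a$in_ring), a$num_h / 4,
    hist, mol$mw / 500, mol$logp / 10, mol$tpsa / 100
  )
  colnames(out) <- TRADITIONAL_DESCRIPTOR_NAMES
  out
}

SMILES_TOKEN_REGEX <- paste0(
  "(\\[[^\\]]+\\]|Br|Cl|%[0-9]{2}|[BCNOPSFIbcnosp]|.)"
)

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into atom tokens (bracket expressions, two-letter
#' halogens, organic-subset symbols) and non-atom tokens (digits, bond
#' symbols, branches, dots).
#'
#' @param smiles A SMILES string.
#' @return Character vector of tokens covering the whole string.
#' @export
tokenize_smiles <- function(smiles) {
  m <- gregexpr(SMILES_TOKEN_REGEX, smiles, perl = TRUE)[[1]]
  regmatches(smiles, list(m))[[1]]
}

is_atom_token <- function(tokens) {
  grepl("^\\[", tokens) |
    tokens %in% c("Br", "Cl", "B", "C", "N", "O", "P", "S", "F", "I",
                  "b", "c", "n", "o", "p", "s")
}

#' Map SMILES tokens to atoms
#'
#' Atom tokens are assigned to atoms in left-to-right order over the SMILES
#' string (the parser preserves SMILES atom order, so the k-th atom token
#' corresponds to atom k). Subtokens prefixed with `##` inherit the atom of
#' their parent token; non-atom tokens map to no atom. Atoms left without
#' any token are reported as unmapped and later filled in by neighbour
#' imputation.
#'
#' @param tokens Character vector of tokens (see [tokenize_smiles()]).
#' @param mol The parsed `hmol` molecule the tokens describe.
#' @return A list with `token_atom` (per-token atom index or `NA`),
#'   `atom_tokens` (per-atom list of token indices) and `unmapped`
#'   (atom indices with no tokens).
#' @export
map_tokens_to_atoms <- function(tokens, mol) {
  n <- nrow(mol$atoms)
  token_atom <- rep(NA_integer_, length(tokens))
  atom_cursor <- 0L
  last_atom <- NA_integer_
  atomish <- is_atom_token(tokens)
  for (i in seq_along(tokens)) {
    if (startsWith(tokens[i], "##")) {
      token_atom[i] <- last_atom
    } else if (atomish[i]) {
      atom_cursor <- atom_cursor + 1L
      if (atom_cursor <= n) {
        token_atom[i] <- atom_cursor
        last_atom <- atom_cursor
      }
    }
  }
  atom_tokens <- lapply(seq_len(n), function(v) which(token_atom == v))
  list(
    token_atom = token_atom,
    atom_tokens = atom_tokens,
    unmapped = which(vapply(atom_tokens, length, 0L) == 0L)
  )
}

#' Create an embedding provider
#'
#' The `"stub"` provider is fully deterministic and needs no download: each
#' distinct token text is mapped to a hash-seeded pseudo-random unit vector,
#' so identical SMILES produce identical embeddings on every machine. A
#' pretrained chemical-language-model provider can be supplied by the user
#' as a list with the same `tokenize`/`embed` interface.
#'
#' @param type Currently `"stub"`.
#' @param width Embedding width (default 32).
#' @return A list with fields `type`, `width`, `tokenize(smiles)` and
#'   `embed(tokens)`.
#' @export
embedding_provider <- function(type = "stub", width = 32L) {
  stopifnot(identical(type, "stub"), width >= 1)
  width <- as.integer(width)
  embed_one <- function(text) {
    v <- 2 * minstd_stream(strhash(paste0("hypermol-stub|", text)), width) - 1
    v / sqrt(sum(v^2))
  }
  cache <- new.env(parent = emptyenv())
  structure(list(
    type = "stub",
    width = width,
    tokenize = tokenize_smiles,
    embed = function(tokens) {
      out <- matrix(0, length(tokens), width)
      for (i in seq_along(tokens)) {
        key <- tokens[i]
        if (!exists(key, envir = cache, inherits = FALSE)) {
          assign(key, embed_one(key), envir = cache)
        }
        out[i, ] <- get(key, envir = cache)
      }
      out
    }
  ), class = "embedding_provider")
}

#' Aggregate token embeddings onto atoms
#'
#' When several tokens map to one atom their embeddings are combined by
#' attention-weighted averaging: weights are a softmax over a scalar score
#' per token. With the frozen stub provider no scores are trained and the
#' weights reduce to uniform `1/|T_v|`. Weights always sum to 1 per atom.
#'
#' @param map Token-atom map from [map_tokens_to_atoms()].
#' @param z Token embedding matrix (one row per token).
#' @param scores Optional per-token scalar scores; `NULL` means uniform.
#' @return Matrix of per-atom semantic embeddings; unmapped atoms are zero
#'   rows (fill them with [impute_unmapped()]).
#' @export
aggregate_token_embeddings <- function(map, z, scores = NULL) {
  n <- length(map$atom_tokens)
  out <- matrix(0, n, ncol(z))
  for (v in seq_len(n)) {
    tv <- map$atom_tokens[[v]]
    if (!length(tv)) next
    w <- if (is.null(scores)) rep(1 / length(tv), length(tv)) else {
      s <- scores[tv]
      e <- exp(s - max(s))
      e / sum(e)
    }
    out[v, ] <- crossprod(z[tv, , drop = FALSE], w)
  }
  out
}

#' Impute semantic embeddings for unmapped atoms
#'
#' Each unmapped atom receives the mean of its already-resolved neighbours'
#' embeddings; passes are iterated to a fixed point so chains of unmapped
#' atoms resolve progressively. Atoms that remain unresolved (unmapped and
#' isolated) fall back to the zero vector.
#'
#' @param map Token-atom map.
#' @param mol The molecule (for bonds).
#' @param h_bert Per-atom embedding matrix with zero rows for unmapped atoms.
#' @return Completed embedding matrix.
#' @export
impute_unmapped <- function(map, mol, h_bert) {
  resolved <- rep(TRUE, nrow(h_bert))
  resolved[map$unmapped] <- FALSE
  if (all(resolved)) return(h_bert)
  adj <- adjacency_list(mol)
  repeat {
    progressed <- FALSE
    for (v in which(!resolved)) {
      nbrs <- adj[[v]]
      ok <- nbrs[resolved[nbrs]]
      if (length(ok)) {
        h_bert[v, ] <- colMeans(h_bert[ok, , drop = FALSE])
        resolved[v] <- TRUE
        progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  h_bert # never-resolved atoms keep the zero vector
}

#' Per-atom semantic embeddings for one molecule
#'
#' Tokenize, embed, project tokens onto atoms and impute unmapped atoms.
#'
#' @param mol An `hmol` molecule.
#' @param provider An [embedding_provider()].
#' @return Matrix of per-atom embeddings.
#' @export
semantic_embeddings <- function(mol, provider = embedding_provider()) {
  tokens <- provider$tokenize(mol$smiles)
  z <- provider$embed(tokens)
  map <- map_tokens_to_atoms(tokens, mol)
  impute_unmapped(map, mol, aggregate_token_embeddings(map, z))
}

#' Fusion configuration for the two feature modalities
#'
#' @param w_bert,w_trad Non-negative modality weights (defaults 1, 1).
#' @param modality `"both"`, `"traditional"` (drops the semantic block:
#'   the Traditional_only ablation) or `"bert"` (drops the descriptor
#'   block: the ChemBERTa_only ablation). The model input width shrinks
#'   accordingly.
#' @return A list of class `fusion_control`.
#' @export
fusion_control <- function(w_bert = 1, w_trad = 1,
                           modality = c("both", "traditional", "bert")) {
  modality <- match.arg(modality)
  stopifnot(w_bert >= 0, w_trad >= 0, w_bert + w_trad > 0)
  structure(list(w_bert = w_bert, w_trad = w_trad, modality = modality),
            class = "fusion_control")
}

#' Fit z-score normalisation statistics
#'
#' Per-feature means and standard deviations, fitted once on the atoms of
#' the training split only (validation and test rows never contribute).
#'
#' @param x Numeric matrix (rows = training-split atoms).
#' @return List with `mean` and `sd` vectors.
#' @export
fit_zscore <- function(x) {
  list(mean = colMeans(x), sd = apply(x, 2, stats::sd))
}

apply_zscore <- function(x, stats) {
  centered <- sweep(x, 2, stats$mean, "-")
  sd <- stats$sd
  sd[!is.finite(sd) | sd == 0] <- Inf # zero-variance features map to 0
  sweep(centered, 2, sd, "/")
}

#' Fuse semantic and traditional atom features
#'
#' `h0 = concat(w_bert * zscore(h_bert), w_trad * zscore(h_trad))`. Under an
#' ablation the excluded modality is dropped entirely (the fused width
#' shrinks), mirroring the feature-source ablation variants.
#'
#' @param h_bert,h_trad Per-atom feature matrices.
#' @param stats List with `bert` and `trad` z-score statistics from
#'   [fit_zscore()].
#' @param control A [fusion_control()].
#' @return Fused per-atom matrix `h0`.
#' @export
fuse_features <- function(h_bert, h_trad, stats, control = fusion_control()) {
  if (is.null(stats$bert) && control$modality != "traditional" ||
      is.null(stats$trad) && control$modality != "bert") {
    stop("normalisation statistics not fitted")
  }
  blocks <- list()
  if (control$modality %in% c("both", "bert")) {
    blocks$bert <- control$w_bert * apply_zscore(h_bert, stats$bert)
  }
  if (control$modality %in% c("both", "traditional")) {
    blocks$trad <- control$w_trad * apply_zscore(h_trad, stats$trad)
  }
  do.call(cbind, unname(blocks))
}
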