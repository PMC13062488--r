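# Multihead hypergraph attention network (HGAT).
#
# Two-stage propagation per layer and head k:
#   d_ve = a_v . (W_v h_v) + a_e . (W_e f_e)            raw incidence scores
#   alpha_ve = softmax_{v in e}( LeakyReLU(d_ve) )      per-hyperedge weights
#   m_e    = sum_{v in e} alpha_ve (W_v h_v + W_e f_e)  node -> hyperedge
#   m_v    = sum_{e in E_v} alpha_ve m_e                hyperedge -> node
#   h'     = sigma( concat_k m_v^k + b^l )
# followed by global average pooling over nodes and a 2-layer MLP head.
# Hyperedge features stay the raw 5-vector at every layer; each layer/head
# has its own 5 -> head_dim transform W_e. Gradients are computed
# analytically (verified against finite differences in the test suite).

#' HGAT architecture configuration
#'
#' @param layers Number of propagation layers (default 3).
#' @param heads Number of attention heads per layer (default 4).
#' @param head_dim Hidden width per head (default 64).
#' @param mlp_hidden Width of the prediction head's hidden layer.
#' @param dropout Dropout rate applied to each layer's input during
#'   training only.
#' @param leaky_slope Negative slope of the LeakyReLU on raw scores.
#' @param n_tasks Number of prediction tasks (outputs).
#' @param task `"regression"` or `"classification"` (classification outputs
#'   raw logits; losses are applied by the training loop).
#' @return A list of class `hgat_control`.
#' @export
hgat_control <- function(layers = 3L, heads = 4L, head_dim = 64L,
                         mlp_hidden = 64L, dropout = 0.2, leaky_slope = 0.2,
                         n_tasks = 1L, task = c("regression", "classification")) {
  stopifnot(layers >= 1, heads >= 1, head_dim >= 1, dropout >= 0, dropout < 1)
  structure(list(
    layers = as.integer(layers), heads = as.integer(heads),
    head_dim = as.integer(head_dim), mlp_hidden = as.integer(mlp_hidden),
    dropout = dropout, leaky_slope = leaky_slope,
    n_tasks = as.integer(n_tasks), task = match.arg(task)
  ), class = "hgat_control")
}

xavier <- function(nr, nc) {
  limit <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -limit, limit), nr, nc)
}

#' Initialise HGAT parameters
#'
#' Xavier-uniform initialisation from a seeded generator; the caller's RNG
#' state is untouched.
#'
#' @param config An [hgat_control()].
#' @param input_dim Width of the fused node features entering layer 1.
#' @param edge_dim Width of the hyperedge features (5).
#' @param seed Integer seed.
#' @return Nested parameter list: per layer, per head `W_v`, `W_e`, `a_v`,
#'   `a_e`; per layer bias `b`; and the MLP head `W1`, `b1`, `W2`, `b2`.
#' @export
init_hgat_params <- function(config, input_dim, edge_dim = 5L, seed = 1L) {
  dh <- config$head_dim
  wide <- config$heads * dh
  with_seed(seed, {
    layers <- lapply(seq_len(config$layers), function(l) {
      d_in <- if (l == 1) input_dim else wide
      heads <- lapply(seq_len(config$heads), function(k) {
        list(
          W_v = xavier(d_in, dh),
          W_e = xavier(edge_dim, dh),
          a_v = as.numeric(xavier(dh, 1)),
          a_e = as.numeric(xavier(dh, 1))
        )
      })
      list(heads = heads, b = numeric(wide))
    })
    mlp <- list(
      W1 = xavier(wide, config$mlp_hidden), b1 = numeric(config$mlp_hidden),
      W2 = xavier(config$mlp_hidden, config$n_tasks), b2 = numeric(config$n_tasks)
    )
    list(layers = layers, mlp = mlp)
  })
}

elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
elu_grad <- function(x) ifelse(x > 0, 1, exp(pmin(x, 0)))
lrelu <- function(x, slope) ifelse(x > 0, x, slope * x)
lrelu_grad <- function(x, slope) ifelse(x > 0, 1, slope)

# Numerically stable softmax over groups; `group_idx` is a list of index
# vectors (one per group, in group order) precomputed at batch assembly.
group_softmax <- function(x, group, group_idx) {
  gmax <- vapply(group_idx, function(i) max(x[i]), 0)
  e <- exp(x - gmax[group])
  sums <- as.numeric(rowsum(e, group))
  unname(e / sums[group])
}

#' Assemble a mini-batch from per-molecule hypergraph tensors
#'
#' Concatenates molecules into one block hypergraph (atoms, hyperedges and
#' incidence pairs re-indexed globally) so a whole batch runs through the
#' network in a handful of matrix operations.
#'
#' @param h0_list List of per-molecule fused node feature matrices.
#' @param fe_list List of per-molecule hyperedge feature matrices.
#' @param members_list List of per-molecule lists of hyperedge member
#'   vectors (1-based atom indices local to the molecule).
#' @return A batch object used by [hgat_forward()].
#' @export
hgat_batch <- function(h0_list, fe_list, members_list) {
  stopifnot(length(h0_list) == length(fe_list),
            length(h0_list) == length(members_list))
  n_atoms <- vapply(h0_list, nrow, 0L)
  n_edges <- vapply(fe_list, nrow, 0L)
  atom_off <- cumsum(c(0L, n_atoms))
  edge_off <- cumsum(c(0L, n_edges))
  iv <- integer(0); ie <- integer(0)
  for (g in seq_along(members_list)) {
    for (j in seq_along(members_list[[g]])) {
      mem <- members_list[[g]][[j]]
      iv <- c(iv, mem + atom_off[g])
      ie <- c(ie, rep(j + edge_off[g], length(mem)))
    }
  }
  list(
    H0 = do.call(rbind, h0_list),
    FE = do.call(rbind, fe_list),
    iv = iv, ie = ie,
    edge_groups = split(seq_along(ie), ie),
    n = sum(n_atoms), m = sum(n_edges),
    mol_of_atom = rep(seq_along(n_atoms), n_atoms),
    mol_of_edge = rep(seq_along(n_edges), n_edges),
    n_mols = length(h0_list),
    atoms_per_mol = n_atoms
  )
}

#' Forward pass of the HGAT
#'
#' @param params Parameters from [init_hgat_params()].
#' @param batch A batch from [hgat_batch()].
#' @param config The [hgat_control()] the parameters were built for.
#' @param training Apply dropout (uses the current RNG stream)?
#' @param record Keep the full attention record (per incidence, head and
#'   layer) for interpretability?
#' @return List with `pred` (molecules x tasks), `pooled` molecule
#'   embeddings, `node_states`, `attention` (when recorded) and the cache
#'   consumed by [hgat_backward()].
#' @export
hgat_forward <- function(params, batch, config, training = FALSE, record = FALSE) {
  if (batch$n == 0) stop("empty batch: no atoms")
  iv <- batch$iv; ie <- batch$ie
  H <- batch$H0
  keep <- 1 - config$dropout
  layer_caches <- vector("list", config$layers)
  attention <- if (record) vector("list", config$layers) else NULL
  for (l in seq_len(config$layers)) {
    mask <- NULL
    if (training && config$dropout > 0) {
      mask <- matrix(stats::rbinom(length(H), 1, keep) / keep, nrow(H), ncol(H))
      H <- H * mask
    }
    lp <- params$layers[[l]]
    head_out <- vector("list", config$heads)
    head_cache <- vector("list", config$heads)
    for (k in seq_len(config$heads)) {
      hp <- lp$heads[[k]]
      P <- H %*% hp$W_v
      Q <- batch$FE %*% hp$W_e
      d <- as.numeric(P %*% hp$a_v)[iv] + as.numeric(Q %*% hp$a_e)[ie]
      u <- lrelu(d, config$leaky_slope)
      alpha <- group_softmax(u, ie, batch$edge_groups)
      Me <- unname(rowsum(alpha * P[iv, , drop = FALSE], ie)) + Q
      Nv <- unname(rowsum(alpha * Me[ie, , drop = FALSE], iv))
      head_out[[k]] <- Nv
      head_cache[[k]] <- list(P = P, Q = Q, d = d, alpha = alpha, Me = Me)
    }
    A <- do.call(cbind, head_out)
    A <- sweep(A, 2, lp$b, "+")
    H_next <- elu(A)
    layer_caches[[l]] <- list(H_in = H, mask = mask, A = A, heads = head_cache)
    if (record) {
      attention[[l]] <- do.call(cbind, lapply(head_cache, `[[`, "alpha"))
    }
    H <- H_next
  }
  counts <- as.numeric(batch$atoms_per_mol)
  pooled <- unname(rowsum(H, batch$mol_of_atom)) / counts
  Y1 <- sweep(pooled %*% params$mlp$W1, 2, params$mlp$b1, "+")
  Z1 <- elu(Y1)
  pred <- sweep(Z1 %*% params$mlp$W2, 2, params$mlp$b2, "+")
  structure(list(
    pred = pred, pooled = pooled, node_states = H,
    attention = attention,
    cache = list(layers = layer_caches, Y1 = Y1, Z1 = Z1, H_final = H)
  ), class = "hgat_forward")
}

zero_like <- function(p) utils::relist(rep(0, length(unlist(p))), p)

#' Backward pass of the HGAT
#'
#' Analytic gradients of all parameters given the gradient of the loss with
#' respect to the predictions.
#'
#' @param params,batch,config As in [hgat_forward()].
#' @param forward The object returned by [hgat_forward()].
#' @param dpred Gradient matrix (molecules x tasks).
#' @return Parameter-shaped list of gradients.
#' @export
hgat_backward <- function(params, batch, config, forward, dpred) {
  cache <- forward$cache
  iv <- batch$iv; ie <- batch$ie
  grads <- list(layers = vector("list", config$layers), mlp = NULL)

  # prediction head
  dZ1 <- dpred %*% t(params$mlp$W2)
  gW2 <- t(cache$Z1) %*% dpred
  gb2 <- colSums(dpred)
  dY1 <- dZ1 * elu_grad(cache$Y1)
  gW1 <- t(rowsum(cache$H_final, batch$mol_of_atom) /
             as.numeric(batch$atoms_per_mol)) %*% dY1
  gb1 <- colSums(dY1)
  grads$mlp <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)

  # mean pooling
  dPool <- dY1 %*% t(params$mlp$W1)
  dH <- dPool[batch$mol_of_atom, , drop = FALSE] /
    as.numeric(batch$atoms_per_mol)[batch$mol_of_atom]

  for (l in rev(seq_len(config$layers))) {
    lc <- cache$layers[[l]]
    lp <- params$layers[[l]]
    dA <- dH * elu_grad(lc$A)
    gb <- colSums(dA)
    dh <- config$head_dim
    dH_prev <- matrix(0, nrow(lc$H_in), ncol(lc$H_in))
    head_grads <- vector("list", config$heads)
    for (k in seq_len(config$heads)) {
      hc <- lc$heads[[k]]
      hp <- lp$heads[[k]]
      dN <- dA[, ((k - 1) * dh + 1):(k * dh), drop = FALSE]
      # n_v = sum_e alpha * M_e
      dN_i <- dN[iv, , drop = FALSE]
      Me_i <- hc$Me[ie, , drop = FALSE]
      dM <- rowsum(hc$alpha * dN_i, ie)
      dalpha <- rowSums(dN_i * Me_i)
      # M_e = (sum_v alpha * P_v) + Q_e
      dQ <- dM
      dM_i <- dM[ie, , drop = FALSE]
      P_i <- hc$P[iv, , drop = FALSE]
      dalpha <- dalpha + rowSums(dM_i * P_i)
      dP <- rowsum(hc$alpha * dM_i, iv)
      # softmax over each hyperedge
      sg <- as.numeric(rowsum(hc$alpha * dalpha, ie))
      du <- hc$alpha * (dalpha - sg[ie])
      dd <- du * lrelu_grad(hc$d, config$leaky_slope)
      # d = (P a_v)[iv] + (Q a_e)[ie]
      ga_v <- as.numeric(t(P_i) %*% dd)
      ga_e <- as.numeric(t(hc$Q[ie, , drop = FALSE]) %*% dd)
      dP <- dP + tcrossprod(as.numeric(rowsum(dd, iv)), hp$a_v)
      dQ <- dQ + tcrossprod(as.numeric(rowsum(dd, ie)), hp$a_e)
      gW_v <- t(lc$H_in) %*% dP
      gW_e <- t(batch$FE) %*% dQ
      dH_prev <- dH_prev + dP %*% t(hp$W_v)
      head_grads[[k]] <- list(W_v = gW_v, W_e = gW_e, a_v = ga_v, a_e = ga_e)
    }
    if (!is.null(lc$mask)) dH_prev <- dH_prev * lc$mask
    grads$layers[[l]] <- list(heads = head_grads, b = gb)
    dH <- dH_prev
  }
  grads
}
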