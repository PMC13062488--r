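# Independent dense-matrix reimplementation of the hypergraph attention
# forward pass, written with explicit loops over an N x M incidence matrix.
# Used as the numerical oracle for the sparse implementation; shares no code
# with it.

dense_elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)

dense_hgat_forward <- function(params, h0, fe, members, config) {
  n <- nrow(h0)
  m <- length(members)
  B <- matrix(FALSE, n, m)
  for (j in seq_len(m)) B[members[[j]], j] <- TRUE
  H <- h0
  for (l in seq_len(config$layers)) {
    lp <- params$layers[[l]]
    per_head <- list()
    for (k in seq_len(config$heads)) {
      hp <- lp$heads[[k]]
      P <- H %*% hp$W_v
      Q <- fe %*% hp$W_e
      alpha <- matrix(0, n, m)
      msg <- matrix(0, m, config$head_dim)
      for (j in seq_len(m)) {
        vs <- which(B[, j])
        d <- numeric(length(vs))
        for (t in seq_along(vs)) {
          d[t] <- sum(hp$a_v * P[vs[t], ]) + sum(hp$a_e * Q[j, ])
        }
        u <- ifelse(d > 0, d, config$leaky_slope * d)
        w <- exp(u - max(u))
        w <- w / sum(w)
        alpha[vs, j] <- w
        for (t in seq_along(vs)) {
          msg[j, ] <- msg[j, ] + w[t] * (P[vs[t], ] + Q[j, ])
        }
      }
      nodes <- matrix(0, n, config$head_dim)
      for (v in seq_len(n)) {
        for (j in which(B[v, ])) {
          nodes[v, ] <- nodes[v, ] + alpha[v, j] * msg[j, ]
        }
      }
      per_head[[k]] <- nodes
    }
    A <- do.call(cbind, per_head)
    for (v in seq_len(n)) A[v, ] <- A[v, ] + lp$b
    H <- dense_elu(A)
  }
  pooled <- colMeans(H)
  y1 <- dense_elu(as.numeric(pooled %*% params$mlp$W1) + params$mlp$b1)
  pred <- as.numeric(y1 %*% params$mlp$W2) + params$mlp$b2
  list(pred = pred, pooled = pooled, node_states = H)
}
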