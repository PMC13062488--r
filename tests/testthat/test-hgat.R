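make_cfg <- function(...) {
  hgat_control(dropout = 0, head_dim = 4, mlp_hidden = 6, ...)
}

test_that("attention normalisation behaves as a per-hyperedge softmax", {
  # equal raw scores in a 4-node hyperedge -> uniform quarters
  cfg <- make_cfg(layers = 1, heads = 1)
  rh <- list(h0 = matrix(1, 4, 3, byrow = TRUE), fe = matrix(0.5, 1, 5),
             members = list(1:4))
  params <- init_hgat_params(cfg, input_dim = 3, seed = 2)
  b <- hgat_batch(list(rh$h0), list(rh$fe), list(rh$members))
  fwd <- hgat_forward(params, b, cfg, record = TRUE)
  expect_equal(as.numeric(fwd$attention[[1]]), rep(0.25, 4))

  # singleton hyperedge -> attention exactly 1
  b1 <- hgat_batch(list(matrix(rnorm(3), 1)), list(matrix(runif(5), 1)),
                   list(list(1L)))
  fwd1 <- hgat_forward(params, b1, cfg, record = TRUE)
  expect_equal(as.numeric(fwd1$attention[[1]]), 1)

  # post-activation scores {0, ln 3} -> weights {0.25, 0.75}
  expect_equal(hypermol:::group_softmax(c(0, log(3)), c(1L, 1L), list(1:2)),
               c(0.25, 0.75))
})

test_that("zero parameters give zero raw attention scores and uniform weights", {
  cfg <- make_cfg(layers = 1, heads = 1)
  params <- init_hgat_params(cfg, input_dim = 3, seed = 1)
  params$layers[[1]]$heads[[1]] <- lapply(params$layers[[1]]$heads[[1]], function(p) p * 0)
  rh <- random_hypergraph(5, 2, input_dim = 3, seed = 9)
  b <- hgat_batch(list(rh$h0), list(rh$fe), list(rh$members))
  fwd <- hgat_forward(params, b, cfg, record = TRUE)
  for (j in seq_along(rh$members)) {
    k <- length(rh$members[[j]])
    expect_equal(fwd$attention[[1]][b$ie == j, 1], rep(1 / k, k))
  }
})

test_that("sparse forward pass matches the dense incidence-matrix oracle", {
  set.seed(77)
  for (trial in 1:30) {
    n <- sample(1:8, 1); m <- sample(1:5, 1)
    k <- sample(c(1, 2, 4), 1)
    rh <- random_hypergraph(n, m, input_dim = 6, seed = 1000 + trial)
    cfg <- make_cfg(layers = sample(1:3, 1), heads = k)
    params <- init_hgat_params(cfg, input_dim = 6, seed = trial)
    b <- hgat_batch(list(rh$h0), list(rh$fe), list(rh$members))
    sparse <- hgat_forward(params, b, cfg)
    dense <- dense_hgat_forward(params, rh$h0, rh$fe, rh$members, cfg)
    expect_equal(as.numeric(sparse$pred), dense$pred, tolerance = 1e-5)
    expect_equal(as.numeric(sparse$pooled), dense$pooled, tolerance = 1e-5)
    expect_equal(sparse$node_states, dense$node_states, tolerance = 1e-5,
                 ignore_attr = TRUE)
  }
})

test_that("attention sums to one per hyperedge at every head and layer", {
  set.seed(101)
  for (trial in 1:10) {
    rh <- random_hypergraph(sample(2:8, 1), sample(2:5, 1),
                            input_dim = 5, seed = 300 + trial)
    cfg <- make_cfg(layers = 3, heads = 4)
    params <- init_hgat_params(cfg, input_dim = 5, seed = trial)
    b <- hgat_batch(list(rh$h0), list(rh$fe), list(rh$members))
    fwd <- hgat_forward(params, b, cfg, record = TRUE)
    for (l in 1:3) {
      sums <- rowsum(fwd$attention[[l]], b$ie)
      expect_true(max(abs(sums - 1)) < 1e-6)
    }
  }
})

test_that("analytic gradients match central finite differences", {
  rh1 <- random_hypergraph(5, 3, input_dim = 4, seed = 21)
  rh2 <- random_hypergraph(4, 2, input_dim = 4, seed = 22)
  b <- hgat_batch(list(rh1$h0, rh2$h0), list(rh1$fe, rh2$fe),
                  list(rh1$members, rh2$members))
  cfg <- make_cfg(layers = 2, heads = 2, n_tasks = 2)
  params <- init_hgat_params(cfg, input_dim = 4, seed = 5)
  y <- matrix(c(0.3, -1, 2, 0.5), 2, 2)
  lossfn <- function(p) sum((hgat_forward(p, b, cfg)$pred - y)^2)
  fwd <- hgat_forward(params, b, cfg)
  grads <- hgat_backward(params, b, cfg, fwd, 2 * (fwd$pred - y))
  flat <- unlist(params); gflat <- unlist(grads)
  set.seed(33)
  idx <- sample(length(flat), 60)
  eps <- 1e-6
  num <- vapply(idx, function(i) {
    (lossfn(utils::relist(replace(flat, i, flat[i] + eps), params)) -
       lossfn(utils::relist(replace(flat, i, flat[i] - eps), params))) / (2 * eps)
  }, 0)
  expect_equal(gflat[idx], num, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("permutation of atom labels permutes states but not predictions", {
  rh <- random_hypergraph(7, 4, input_dim = 5, seed = 55)
  cfg <- make_cfg(layers = 2, heads = 2)
  params <- init_hgat_params(cfg, input_dim = 5, seed = 8)
  perm <- with_seed(9, sample(7))
  members_p <- lapply(rh$members, function(m) sort(match(m, perm)))
  # node i of the permuted instance is node perm[i] of the original
  h0_p <- rh$h0[perm, ]
  b <- hgat_batch(list(rh$h0), list(rh$fe), list(rh$members))
  bp <- hgat_batch(list(h0_p), list(rh$fe), list(members_p))
  f <- hgat_forward(params, b, cfg)
  fp <- hgat_forward(params, bp, cfg)
  expect_equal(fp$pred, f$pred, tolerance = 1e-5)
  expect_equal(fp$pooled, f$pooled, tolerance = 1e-5)
  expect_equal(fp$node_states, f$node_states[perm, ], tolerance = 1e-5)
})

test_that("evaluation mode is deterministic; training dropout is not a no-op", {
  rh <- random_hypergraph(6, 3, input_dim = 5, seed = 4)
  cfg <- hgat_control(layers = 2, heads = 2, head_dim = 4, mlp_hidden = 6,
                      dropout = 0.5)
  params <- init_hgat_params(cfg, input_dim = 5, seed = 2)
  b <- hgat_batch(list(rh$h0), list(rh$fe), list(rh$members))
  f1 <- hgat_forward(params, b, cfg)
  f2 <- hgat_forward(params, b, cfg)
  expect_identical(f1$pred, f2$pred)
  set.seed(1); t1 <- hgat_forward(params, b, cfg, training = TRUE)$pred
  set.seed(2); t2 <- hgat_forward(params, b, cfg, training = TRUE)$pred
  expect_false(identical(t1, t2))
})

test_that("every parameter receives gradient signal from a nonzero loss", {
  rh <- random_hypergraph(6, 4, input_dim = 5, seed = 71)
  cfg <- make_cfg(layers = 3, heads = 2)
  params <- init_hgat_params(cfg, input_dim = 5, seed = 3)
  b <- hgat_batch(list(rh$h0), list(rh$fe), list(rh$members))
  fwd <- hgat_forward(params, b, cfg)
  y <- matrix(5, 1, 1)
  grads <- hgat_backward(params, b, cfg, fwd,
                         masked_loss_grad(fwd$pred, y, matrix(1, 1, 1),
                                          "regression")$dpred)
  # check tensor-level gradient norms
  walk <- function(g, path = "") {
    if (is.list(g)) {
      for (nm in seq_along(g)) walk(g[[nm]], paste0(path, "/", nm))
    } else {
      expect_gt(sqrt(sum(g^2)), 0, label = paste("grad norm at", path))
    }
  }
  walk(grads)
})

test_that("node update concatenates heads and degenerate instances run", {
  cfg <- make_cfg(layers = 1, heads = 3)
  params <- init_hgat_params(cfg, input_dim = 4, seed = 6)
  rh <- random_hypergraph(5, 2, input_dim = 4, seed = 13)
  b <- hgat_batch(list(rh$h0), list(rh$fe), list(rh$members))
  fwd <- hgat_forward(params, b, cfg)
  expect_equal(ncol(fwd$node_states), 3 * 4) # K x head width

  # N = 1, M = 1 boundary instance
  tiny <- random_hypergraph(1, 1, input_dim = 4, seed = 14)
  bt <- hgat_batch(list(tiny$h0), list(tiny$fe), list(tiny$members))
  ft <- hgat_forward(params, bt, cfg, record = TRUE)
  expect_equal(dim(ft$pred), c(1, 1))
  expect_equal(as.numeric(ft$attention[[1]]), rep(1, 3))

  # all node states identical -> pooled equals that state
  same <- list(h0 = matrix(rep(c(1, 2, 0.5, -1), each = 3), 3, 4),
               fe = matrix(0.2, 1, 5), members = list(1:3))
  bs <- hgat_batch(list(same$h0), list(same$fe), list(same$members))
  fs <- hgat_forward(params, bs, cfg)
  expect_equal(as.numeric(fs$pooled), as.numeric(fs$node_states[1, ]),
               tolerance = 1e-12)
})

test_that("masked losses ignore missing labels and vanish when all masked", {
  pred <- matrix(c(0.5, -1), 2, 1)
  y <- matrix(c(1, NA), 2, 1)
  mask <- matrix(c(1, 0), 2, 1)
  lr <- masked_loss_grad(pred, y, mask, "regression")
  expect_equal(lr$loss, (0.5 - 1)^2)
  expect_equal(lr$dpred[2, 1], 0)
  lc <- masked_loss_grad(pred, y, mask, "classification")
  expect_equal(lc$dpred[2, 1], 0)
  all_masked <- masked_loss_grad(pred, y, matrix(0, 2, 1), "classification")
  expect_equal(all_masked$loss, 0)
  expect_equal(all_masked$dpred, matrix(0, 2, 1))
})
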