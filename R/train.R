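# Model fitting: masked losses, Adam, early stopping on the validation
# metric, and the user-facing hypermol() front end.

#' Training options
#'
#' @param lr Adam learning rate.
#' @param epochs Maximum number of epochs.
#' @param batch_size Molecules per mini-batch.
#' @param patience Early-stopping patience, in epochs without validation
#'   improvement.
#' @param verbose Print per-epoch progress?
#' @return A list of class `trainer_control`.
#' @export
trainer_control <- function(lr = 1e-3, epochs = 200L, batch_size = 64L,
                            patience = 20L, verbose = FALSE) {
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), verbose = isTRUE(verbose)),
            class = "trainer_control")
}

# Masked losses. mask is 1 where a label exists; a fully masked batch
# contributes zero loss and zero gradient.
masked_loss_grad <- function(pred, y, mask, task) {
  denom <- sum(mask)
  if (denom == 0) {
    return(list(loss = 0, dpred = matrix(0, nrow(pred), ncol(pred))))
  }
  y0 <- ifelse(mask > 0, y, 0)
  if (task == "regression") {
    diff <- (pred - y0) * mask
    list(loss = sum(diff^2) / denom, dpred = 2 * diff / denom)
  } else {
    z <- pred
    # stable log(1 + exp(z)) - y z, masked
    ll <- (pmax(z, 0) - y0 * z + log1p(exp(-abs(z)))) * mask
    p <- 1 / (1 + exp(-z))
    list(loss = sum(ll) / denom, dpred = (p - y0) * mask / denom)
  }
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, flat, gflat, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * gflat
  state$v <- beta2 * state$v + (1 - beta2) * gflat^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(state = state, flat = flat - lr * mhat / (sqrt(vhat) + eps))
}

# Per-molecule graph tensors shared by fitting, prediction and explanation.
featurize_molecules <- function(mols, graph_control, provider, en_table,
                                fg_library = NULL) {
  graphs <- lapply(mols, build_hypergraph, control = graph_control,
                   fg_library = fg_library)
  list(
    graphs = graphs,
    members = lapply(graphs, function(hg) lapply(hg$hyperedges, `[[`, "members")),
    fe = lapply(graphs, hyperedge_features, table = en_table),
    h_trad = lapply(mols, traditional_descriptors),
    h_bert = lapply(mols, semantic_embeddings, provider = provider)
  )
}

fuse_all <- function(feats, stats, fusion) {
  mapply(function(hb, ht) fuse_features(hb, ht, stats, fusion),
         feats$h_bert, feats$h_trad, SIMPLIFY = FALSE)
}

predict_from_tensors <- function(params, config, h0, fe, members, chunk = 512L) {
  n <- length(h0)
  preds <- vector("list", ceiling(n / chunk))
  for (ci in seq_along(preds)) {
    idx <- ((ci - 1L) * chunk + 1L):min(ci * chunk, n)
    b <- hgat_batch(h0[idx], fe[idx], members[idx])
    preds[[ci]] <- hgat_forward(params, b, config)$pred
  }
  do.call(rbind, preds)
}

#' Fit a hypergraph attention model for molecular property prediction
#'
#' The response side of `formula` names the task column(s) (use
#' `cbind(t1, t2)` for multi-task data); the right-hand side names the
#' SMILES column. Molecules are parsed, turned into hypergraphs with
#' 5-dimensional hyperedge features, atom features are fused from semantic
#' token embeddings and physicochemical descriptors (normalisation
#' statistics fitted on the training split only), and a multihead
#' hypergraph attention network is trained with Adam under a masked loss,
#' early-stopped on the validation metric.
#'
#' @param formula e.g. `y ~ smiles` or `cbind(task1, task2) ~ smiles`.
#' @param data A data.frame, or an `hmol_dataset` (then `formula` may be
#'   omitted).
#' @param task `"regression"` or `"classification"`.
#' @param control An [hgat_control()]; `n_tasks` is filled in from the data.
#' @param trainer A [trainer_control()].
#' @param fusion A [fusion_control()].
#' @param graph A [hypergraph_control()].
#' @param provider An [embedding_provider()].
#' @param split An `hmol_split`, or `NULL` to scaffold-split with
#'   `fractions`.
#' @param fractions Train/validation/test fractions for the default
#'   scaffold split.
#' @param stratified Stratify the scaffold split by the first task's labels?
#'   Defaults to `TRUE` for classification.
#' @param seed Integer seed governing splitting, initialisation, shuffling
#'   and dropout.
#' @return An object of class `hypermol`.
#' @examples
#' \dontrun{
#' sim <- simulate_regression(n = 200, seed = 1)
#' fit <- hypermol(y ~ smiles, sim, task = "regression",
#'                 control = hgat_control(head_dim = 8),
#'                 trainer = trainer_control(epochs = 30))
#' predict(fit, "OCC(O)CO")
#' }
#' @export
hypermol <- function(formula = NULL, data, task = c("regression", "classification"),
                     control = hgat_control(), trainer = trainer_control(),
                     fusion = fusion_control(), graph = hypergraph_control(),
                     provider = embedding_provider(), split = NULL,
                     fractions = c(0.8, 0.1, 0.1), stratified = NULL,
                     seed = 1L) {
  cl <- match.call()
  task <- match.arg(task)
  smiles_col <- "smiles"
  if (inherits(data, "hmol_dataset")) {
    ds <- data
    task <- ds$task
  } else {
    stopifnot(inherits(formula, "formula"))
    smiles_col <- all.vars(formula[[3]])
    if (length(smiles_col) != 1) stop("right-hand side must be one SMILES column")
    task_cols <- all.vars(formula[[2]])
    ds <- as_dataset(data[[smiles_col]], as.matrix(data[task_cols]), task, task_cols)
  }
  n <- length(ds$smiles)
  if (n < 2) stop("need at least two parseable molecules")
  control$n_tasks <- ncol(ds$y)
  control$task <- task
  if (is.null(stratified)) stratified <- task == "classification"

  if (is.null(split)) {
    split <- scaffold_split(
      ds$scaffolds, fractions = fractions,
      stratify = if (stratified) ds$y[, 1] else NULL, seed = seed
    )
  }
  if (!length(split$train)) stop("empty training split")

  en_table <- electronegativity_table()
  feats <- featurize_molecules(ds$mols, graph, provider, en_table)
  stats <- list(
    bert = fit_zscore(do.call(rbind, feats$h_bert[split$train])),
    trad = fit_zscore(do.call(rbind, feats$h_trad[split$train]))
  )
  h0 <- fuse_all(feats, stats, fusion)
  input_dim <- ncol(h0[[1]])

  params <- init_hgat_params(control, input_dim, seed = seed)
  flat <- unlist(params)
  opt <- adam_init(length(flat))
  # early stopping monitors the validation loss (masked MSE / log-loss):
  # unlike AUC it keeps improving after the ranking saturates, which also
  # keeps sharpening the attention maps used for interpretation
  best_loss <- Inf
  best_flat <- flat
  stall <- 0L
  history <- list()

  valid_idx <- if (length(split$valid)) split$valid else split$train
  valid_batch <- hgat_batch(h0[valid_idx], feats$fe[valid_idx],
                            feats$members[valid_idx])
  valid_y <- ds$y[valid_idx, , drop = FALSE]
  valid_mask <- ds$mask[valid_idx, , drop = FALSE]
  with_seed(seed + 1L, {
    for (epoch in seq_len(trainer$epochs)) {
      ord <- sample(split$train)
      n_batches <- ceiling(length(ord) / trainer$batch_size)
      epoch_loss <- 0
      for (bi in seq_len(n_batches)) {
        idx <- ord[((bi - 1L) * trainer$batch_size + 1L):
                     min(bi * trainer$batch_size, length(ord))]
        b <- hgat_batch(h0[idx], feats$fe[idx], feats$members[idx])
        fwd <- hgat_forward(params, b, control, training = TRUE)
        lg <- masked_loss_grad(fwd$pred, ds$y[idx, , drop = FALSE],
                               ds$mask[idx, , drop = FALSE], task)
        epoch_loss <- epoch_loss + lg$loss * length(idx)
        grads <- hgat_backward(params, b, control, fwd, lg$dpred)
        step <- adam_step(opt, flat, unlist(grads), trainer$lr)
        opt <- step$state
        flat <- step$flat
        params <- utils::relist(flat, params)
      }
      vfwd <- hgat_forward(params, valid_batch, control)
      vloss <- masked_loss_grad(vfwd$pred, valid_y, valid_mask, task)$loss
      vm <- evaluate_predictions(valid_y, vfwd$pred, task)$aggregate
      history[[epoch]] <- c(epoch = epoch,
                            train_loss = epoch_loss / length(split$train),
                            valid_loss = vloss, valid_metric = vm)
      if (trainer$verbose) {
        message(sprintf("epoch %3d  loss %.4f  valid loss %.4f  valid %.4f",
                        epoch, epoch_loss / length(split$train), vloss, vm))
      }
      if (vloss < best_loss - 1e-7) {
        best_loss <- vloss
        best_flat <- flat
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= trainer$patience) break
      }
    }
  })
  params <- utils::relist(best_flat, params)

  preds <- list()
  metrics <- list()
  for (part in c("train", "valid", "test")) {
    idx <- split[[part]]
    if (!length(idx)) next
    p <- predict_from_tensors(params, control, h0[idx], feats$fe[idx],
                              feats$members[idx])
    if (task == "classification") p_resp <- 1 / (1 + exp(-p)) else p_resp <- p
    preds[[part]] <- list(index = idx, pred = p_resp,
                          y = ds$y[idx, , drop = FALSE])
    metrics[[part]] <- evaluate_predictions(ds$y[idx, , drop = FALSE], p, task)
  }

  structure(list(
    call = cl,
    task = task,
    task_names = ds$task_names,
    smiles_col = smiles_col,
    params = params,
    control = control,
    trainer = trainer,
    fusion = fusion,
    graph = graph,
    provider = list(type = provider$type, width = provider$width),
    stats = stats,
    input_dim = input_dim,
    split = split,
    seed = seed,
    history = do.call(rbind, history),
    predictions = preds,
    metrics = metrics,
    n_dropped = ds$n_dropped
  ), class = "hypermol")
}

rebuild_provider <- function(object) {
  embedding_provider(object$provider$type, object$provider$width)
}

#' Predict molecular properties from a fitted model
#'
#' @param object A fitted `hypermol` model.
#' @param newdata Character vector of SMILES, or a data.frame containing
#'   the SMILES column used at fit time.
#' @param type `"response"` (probabilities for classification, values for
#'   regression) or `"link"` (raw logits).
#' @param ... Unused.
#' @return Numeric matrix, one row per molecule, one column per task. Rows
#'   for unparseable SMILES are `NA` (with a warning).
#' @export
predict.hypermol <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) {
    newdata <- newdata[[object$smiles_col %||% "smiles"]]
  }
  smiles <- as.character(newdata)
  mols <- parse_molecules(smiles)
  bad <- vapply(mols, inherits, TRUE, "hmol_parse_error")
  if (any(bad)) warning(sum(bad), " unparseable SMILES; returning NA rows")
  out <- matrix(NA_real_, length(smiles), object$control$n_tasks,
                dimnames = list(NULL, object$task_names))
  if (all(bad)) return(out)
  feats <- featurize_molecules(mols[!bad], object$graph,
                               rebuild_provider(object),
                               electronegativity_table())
  h0 <- fuse_all(feats, object$stats, object$fusion)
  p <- predict_from_tensors(object$params, object$control, h0, feats$fe,
                            feats$members)
  if (object$task == "classification" && type == "response") {
    p <- 1 / (1 + exp(-p))
  }
  out[!bad, ] <- p
  out
}

#' @export
print.hypermol <- function(x, ...) {
  cat("<hypermol> multihead hypergraph attention model\n")
  cat("  task: ", x$task, " (", length(x$task_names), " task(s))\n", sep = "")
  cat("  architecture: ", x$control$layers, " layers x ", x$control$heads,
      " heads x ", x$control$head_dim, " dims; input width ", x$input_dim,
      "\n", sep = "")
  cat("  split: ", length(x$split$train), "/", length(x$split$valid), "/",
      length(x$split$test), " (scaffold)\n", sep = "")
  for (part in names(x$metrics)) {
    m <- x$metrics[[part]]
    cat(sprintf("  %s %s: %.4f\n", part, m$metric, m$aggregate))
  }
  invisible(x)
}

#' @export
summary.hypermol <- function(object, ...) {
  out <- list(
    task = object$task,
    task_names = object$task_names,
    n_parameters = length(unlist(object$params)),
    epochs_run = nrow(object$history),
    metrics = object$metrics,
    per_task = lapply(object$metrics, `[[`, "per_task")
  )
  class(out) <- "summary.hypermol"
  out
}

#' @export
print.summary.hypermol <- function(x, ...) {
  cat("hypermol model summary\n")
  cat("  parameters:", x$n_parameters, "  epochs run:", x$epochs_run, "\n")
  for (part in names(x$metrics)) {
    m <- x$metrics[[part]]
    cat(sprintf("  %s %s = %.4f\n", part, m$metric, m$aggregate))
    if (length(m$per_task) > 1) {
      for (t in names(m$per_task)) {
        cat(sprintf("    %s: %.4f\n", t, m$per_task[t]))
      }
    }
  }
  invisible(x)
}

#' @export
coef.hypermol <- function(object, ...) object$params

#' Residuals of a fitted regression model
#'
#' @param object A fitted `hypermol` regression model.
#' @param part Which split to report (`"test"`, `"valid"` or `"train"`).
#' @param ... Unused.
#' @return Matrix of observed minus predicted values.
#' @export
residuals.hypermol <- function(object, part = "test", ...) {
  if (object$task != "regression") stop("residuals are defined for regression fits")
  p <- object$predictions[[part]]
  if (is.null(p)) stop("no predictions stored for part '", part, "'")
  p$y - p$pred
}

#' Plot training history
#'
#' Training loss and validation metric per epoch.
#'
#' @param x A fitted `hypermol` model.
#' @param ... Passed to [plot()].
#' @export
plot.hypermol <- function(x, ...) {
  h <- as.data.frame(x$history)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
       ylab = "training loss", main = "loss", ...)
  plot(h$epoch, h$valid_metric, type = "l", xlab = "epoch",
       ylab = if (x$task == "classification") "validation AUC" else "validation RMSE",
       main = "validation", ...)
  invisible(x)
}

#' Repeat training over several seeds
#'
#' Re-fits the model once per seed (fresh split, initialisation, shuffling
#' and dropout stream) and reports test-set metrics as mean and sample SD
#' over seeds. Failing runs are flagged and excluded from the aggregate.
#'
#' @param formula,data,... Passed to [hypermol()].
#' @param seeds Integer vector of seeds (default `1:5`).
#' @return An object of class `hypermol_repeats` with per-seed values,
#'   `mean`, `sd` and failure flags; serialisable with
#'   [jsonlite::toJSON()] via `as.list()`.
#' @export
run_repeats <- function(formula = NULL, data, seeds = 1:5, ...) {
  stopifnot(length(seeds) >= 2)
  runs <- lapply(seeds, function(s) {
    tryCatch({
      fit <- hypermol(formula, data, seed = s, ...)
      list(seed = s, ok = TRUE,
           metric = fit$metrics$test$aggregate %||% NA_real_,
           per_task = fit$metrics$test$per_task)
    }, error = function(e) list(seed = s, ok = FALSE, error = conditionMessage(e),
                                metric = NA_real_))
  })
  vals <- vapply(runs, `[[`, 0, "metric")
  structure(list(
    seeds = seeds,
    runs = runs,
    values = vals,
    mean = mean(vals, na.rm = TRUE),
    sd = stats::sd(vals[!is.na(vals)]),
    n_failed = sum(!vapply(runs, `[[`, TRUE, "ok"))
  ), class = "hypermol_repeats")
}

#' @export
print.hypermol_repeats <- function(x, ...) {
  cat("<repeated runs> ", length(x$seeds), " seeds: mean ",
      sprintf("%.4f", x$mean), " +/- ", sprintf("%.4f", x$sd),
      if (x$n_failed) paste0(" (", x$n_failed, " failed)"), "\n", sep = "")
  invisible(x)
}

#' @export
as.list.hypermol_repeats <- function(x, ...) {
  list(seeds = x$seeds, values = x$values, mean = x$mean, sd = x$sd,
       n_failed = x$n_failed)
}
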