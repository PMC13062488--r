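# Evaluation metrics. AUC uses the rank (Mann-Whitney) formulation, which
# counts tied scores as 1/2; RMSE and MAE are the direct formulas.

#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive is scored above a
#' randomly chosen negative, ties counting one half.
#'
#' @param labels Binary vector (0/1); `NA`s are dropped together with their
#'   scores.
#' @param scores Numeric prediction scores.
#' @return AUC in \[0, 1\], or `NA` with a warning when only one class is
#'   present.
#' @examples
#' auc_roc(c(1, 0, 1, 0), c(0.9, 0.8, 0.3, 0.2)) # 0.75
#' @export
auc_roc <- function(labels, scores) {
  if (length(labels) != length(scores)) stop("labels and scores differ in length")
  ok <- !is.na(labels) & !is.na(scores)
  labels <- labels[ok]; scores <- scores[ok]
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Root mean squared error
#'
#' @param y Observed values.
#' @param yhat Predicted values.
#' @return `sqrt(mean((yhat - y)^2))` over non-missing pairs.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat differ in length")
  ok <- !is.na(y) & !is.na(yhat)
  sqrt(mean((yhat[ok] - y[ok])^2))
}

#' Mean absolute error
#'
#' @inheritParams rmse
#' @return `mean(abs(yhat - y))` over non-missing pairs.
#' @export
mae <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat differ in length")
  ok <- !is.na(y) & !is.na(yhat)
  mean(abs(yhat[ok] - y[ok]))
}

# Per-task metrics plus their aggregate (mean over tasks for which the
# metric is defined). y, pred: molecules x tasks matrices.
evaluate_predictions <- function(y, pred, task) {
  per_task <- vapply(seq_len(ncol(y)), function(t) {
    if (task == "classification") {
      suppressWarnings(auc_roc(y[, t], pred[, t]))
    } else {
      rmse(y[, t], pred[, t])
    }
  }, 0)
  names(per_task) <- colnames(y)
  aggregate <- if (all(is.na(per_task))) NA_real_ else mean(per_task, na.rm = TRUE)
  list(
    metric = if (task == "classification") "auc" else "rmse",
    per_task = per_task,
    aggregate = aggregate,
    mae = if (task == "regression") {
      mean(vapply(seq_len(ncol(y)), function(t) mae(y[, t], pred[, t]), 0))
    } else NA_real_
  )
}
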