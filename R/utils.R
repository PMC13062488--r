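`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library code never perturbs user-level randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic polynomial string hash on [1, 2^31 - 2]; platform-independent
# (all arithmetic stays below 2^53 so doubles are exact).
strhash <- function(s) {
  codes <- utf8ToInt(enc2utf8(s))
  h <- 17
  m <- 2147483647
  for (code in codes) h <- (h * 31 + code) %% m
  as.numeric(h %% (m - 2) + 1)
}

# Park-Miller minimal-standard generator: deterministic uniform stream in
# (0, 1) from an integer state, independent of R's RNG.
minstd_stream <- function(seed, n) {
  x <- as.numeric(seed)
  m <- 2147483647
  if (x <= 0 || x >= m) x <- (abs(x) %% (m - 2)) + 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- (16807 * x) %% m
    out[i] <- x / m
  }
  out
}

stop_hypermol <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "hypermol_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}
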