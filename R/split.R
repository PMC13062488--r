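# Bemis-Murcko scaffold splitting. Molecules sharing a scaffold are assigned
# to the same partition, preventing near-duplicate leakage between splits.

#' Scaffold-grouped train/validation/test split
#'
#' Molecules are grouped by Bemis-Murcko scaffold (acyclic molecules all
#' share the empty-scaffold group). Whole groups are assigned largest first
#' - ties broken by a seed-dependent shuffle, then by scaffold string - to
#' the training partition until it reaches its target fraction, then to
#' validation, then test. The stratified variant runs the same packing
#' separately within label strata (majority label of each group, first task)
#' to preserve the class distribution.
#'
#' @param scaffolds Character vector of scaffold SMILES, one per molecule
#'   (see the `scaffold` field of [parse_molecule()]).
#' @param fractions Train/validation/test fractions, summing to 1.
#' @param stratify Optional label vector (single-task classification) used
#'   to stratify group assignment.
#' @param seed Integer seed controlling tie ordering only.
#' @return An object of class `hmol_split`: integer index vectors `train`,
#'   `valid`, `test` (disjoint, covering all molecules), plus the scaffold
#'   grouping.
#' @export
scaffold_split <- function(scaffolds, fractions = c(0.8, 0.1, 0.1),
                           stratify = NULL, seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, length(fractions) == 3)
  scaffolds[is.na(scaffolds)] <- ""
  n <- length(scaffolds)
  groups <- split(seq_len(n), scaffolds)
  if (length(groups) < 3) {
    warning("fewer scaffold groups than partitions; some partitions are empty")
  }
  assign_groups <- function(groups, caps) {
    sizes <- vapply(groups, length, 0L)
    keys <- names(groups)
    shuffle <- with_seed(seed, sample.int(length(groups)))
    ord <- order(-sizes, shuffle, keys)
    out <- list(train = integer(0), valid = integer(0), test = integer(0))
    for (g in ord) {
      idx <- groups[[g]]
      if (length(out$train) + length(idx) <= caps[1]) {
        out$train <- c(out$train, idx)
      } else if (length(out$valid) + length(idx) <= caps[2]) {
        out$valid <- c(out$valid, idx)
      } else if (length(out$test) + length(idx) <= caps[3]) {
        out$test <- c(out$test, idx)
      } else {
        out$train <- c(out$train, idx) # nothing fits: train absorbs overflow
      }
    }
    out
  }
  if (is.null(stratify)) {
    parts <- assign_groups(groups, caps = fractions * n)
  } else {
    stopifnot(length(stratify) == n)
    strata_of_group <- vapply(groups, function(idx) {
      lab <- stratify[idx]
      lab <- lab[!is.na(lab)]
      if (!length(lab)) "none" else as.character(round(mean(lab)))
    }, "")
    parts <- list(train = integer(0), valid = integer(0), test = integer(0))
    for (s in sort(unique(strata_of_group))) {
      sub <- groups[strata_of_group == s]
      n_s <- sum(vapply(sub, length, 0L))
      p <- assign_groups(sub, caps = fractions * n_s)
      parts$train <- c(parts$train, p$train)
      parts$valid <- c(parts$valid, p$valid)
      parts$test <- c(parts$test, p$test)
    }
  }
  parts <- lapply(parts, sort)
  stopifnot(
    !anyDuplicated(c(parts$train, parts$valid, parts$test)),
    length(c(parts$train, parts$valid, parts$test)) == n
  )
  structure(
    list(train = parts$train, valid = parts$valid, test = parts$test,
         scaffolds = scaffolds, fractions = fractions, seed = seed),
    class = "hmol_split"
  )
}

#' @export
print.hmol_split <- function(x, ...) {
  cat("<scaffold split> train/valid/test =",
      length(x$train), "/", length(x$valid), "/", length(x$test),
      " (", length(unique(x$scaffolds)), "scaffold groups )\n")
  invisible(x)
}
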