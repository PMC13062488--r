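# Dataset I/O: CSV tables with one SMILES column and one or more task
# columns; empty cells are missing labels (allowed for multi-task
# classification and masked out of the loss).

#' Load a molecular property dataset from CSV
#'
#' Parses every SMILES through the chemistry backend; rows whose SMILES
#' cannot be parsed are dropped with a warning reporting the count.
#'
#' @param path CSV file with a header row.
#' @param smiles_col Name of the SMILES column (default `"smiles"`).
#' @param tasks Character vector of task column names; default: every other
#'   column.
#' @param task `"regression"` or `"classification"`.
#' @return A list of class `hmol_dataset`: `smiles`, parsed `mols`,
#'   label matrix `y` (NA = missing), `mask`, `task`, `task_names`,
#'   `scaffolds` and the number of dropped rows.
#' @export
load_dataset <- function(path, smiles_col = "smiles", tasks = NULL,
                         task = c("regression", "classification")) {
  task <- match.arg(task)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!smiles_col %in% names(df)) {
    stop("missing SMILES column '", smiles_col, "'; columns present: ",
         paste(names(df), collapse = ", "))
  }
  if (is.null(tasks)) tasks <- setdiff(names(df), smiles_col)
  missing_tasks <- setdiff(tasks, names(df))
  if (length(missing_tasks)) {
    stop("missing task column(s): ", paste(missing_tasks, collapse = ", "))
  }
  if (!length(tasks)) stop("dataset must have at least one task column")
  as_dataset(df[[smiles_col]], as.matrix(df[, tasks, drop = FALSE]), task, tasks)
}

as_dataset <- function(smiles, y, task, task_names) {
  y <- matrix(as.numeric(y), nrow = length(smiles),
              dimnames = list(NULL, task_names))
  mols <- parse_molecules(as.character(smiles))
  bad <- vapply(mols, inherits, TRUE, "hmol_parse_error")
  if (any(bad)) {
    warning("dropped ", sum(bad), " row(s) with unparseable SMILES")
  }
  keep <- which(!bad)
  mols <- mols[keep]
  structure(list(
    smiles = as.character(smiles)[keep],
    mols = mols,
    y = y[keep, , drop = FALSE],
    mask = 1 * !is.na(y[keep, , drop = FALSE]),
    task = task,
    task_names = task_names,
    scaffolds = vapply(mols, function(m) m$scaffold %||% "", ""),
    n_dropped = sum(bad)
  ), class = "hmol_dataset")
}

#' @export
print.hmol_dataset <- function(x, ...) {
  cat("<dataset> ", length(x$smiles), " molecules, ",
      length(x$task_names), " ", x$task, " task(s)",
      if (x$n_dropped) paste0(" (", x$n_dropped, " rows dropped)"), "\n", sep = "")
  invisible(x)
}
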