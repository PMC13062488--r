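# Bridge to the bundled RDKit helper script. One call handles a whole batch
# of SMILES: parsing, per-atom attributes, Gasteiger charges, molecule-level
# descriptors, SSSR rings, SMARTS matches for both bundled libraries and
# Bemis-Murcko scaffolds. All indices are converted to 1-based on ingestion.

.hypermol_cache <- new.env(parent = emptyenv())

hypermol_python <- function() {
  Sys.getenv("HYPERMOL_PYTHON", unset = "python")
}

rdkit_call <- function(request) {
  helper <- system.file("python", "rdkit_helper.py", package = "hypermol")
  if (helper == "") stop("bundled rdkit helper not found; is hypermol installed?")
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  errfile <- tempfile(fileext = ".txt")
  on.exit(unlink(c(infile, outfile, errfile)))
  jsonlite::write_json(request, infile, auto_unbox = TRUE, digits = NA, null = "null")
  status <- suppressWarnings(system2(
    hypermol_python(), shQuote(helper),
    stdin = infile, stdout = outfile, stderr = errfile
  ))
  if (!identical(status, 0L)) {
    err <- tryCatch(paste(readLines(errfile), collapse = "\n"), error = function(e) "")
    stop("rdkit helper failed (exit ", status, "):\n", err)
  }
  jsonlite::fromJSON(outfile, simplifyVector = FALSE)
}

as_library_payload <- function(lib) {
  lapply(seq_len(nrow(lib)), function(i) {
    list(name = lib$name[i], smarts = lib$smarts[i])
  })
}

# matches come nested set -> pattern -> match; convert each match from a
# 0-based JSON list to a 1-based integer vector
ingest_matches <- function(raw) {
  lapply(raw, function(per_set) {
    lapply(per_set, function(per_pattern) {
      lapply(per_pattern, function(m) as.integer(unlist(m)) + 1L)
    })
  })
}

ingest_molecule <- function(raw) {
  if (!is.null(raw$error)) {
    return(structure(
      list(smiles = raw$smiles, message = raw$error),
      class = "hmol_parse_error"
    ))
  }
  a <- raw$atoms
  gast <- vapply(a$gasteiger, function(g) if (is.null(g)) NA_real_ else as.numeric(g), 0)
  n_bad_charge <- sum(!is.finite(gast))
  gast[!is.finite(gast)] <- 0
  atoms <- data.frame(
    symbol = unlist(a$symbol),
    z = as.integer(unlist(a$z)),
    degree = as.integer(unlist(a$degree)),
    formal_charge = as.integer(unlist(a$formal_charge)),
    aromatic = as.logical(unlist(a$aromatic)),
    in_ring = as.logical(unlist(a$in_ring)),
    num_h = as.integer(unlist(a$num_h)),
    radicals = as.integer(unlist(a$radicals)),
    gasteiger = gast,
    stringsAsFactors = FALSE
  )
  bonds <- if (length(raw$bonds)) {
    data.frame(
      a1 = vapply(raw$bonds, function(b) as.integer(b[[1]]), 0L) + 1L,
      a2 = vapply(raw$bonds, function(b) as.integer(b[[2]]), 0L) + 1L,
      order = vapply(raw$bonds, function(b) as.character(b[[3]]), ""),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(a1 = integer(), a2 = integer(), order = character())
  }
  structure(
    list(
      smiles = raw$smiles,
      canonical_smiles = raw$canonical_smiles,
      atoms = atoms,
      bonds = bonds,
      rings = lapply(raw$rings, function(r) as.integer(unlist(r)) + 1L),
      mw = as.numeric(raw$mw),
      logp = as.numeric(raw$logp),
      tpsa = as.numeric(raw$tpsa),
      scaffold = raw$scaffold %||% NA_character_,
      matches = ingest_matches(raw$matches),
      n_undefined_charges = n_bad_charge
    ),
    class = "hmol"
  )
}

#' Parse a batch of SMILES strings
#'
#' Runs the bundled RDKit helper once for the whole batch and returns one
#' molecule record per input. Unparseable SMILES yield `hmol_parse_error`
#' records instead of molecules; dataset loaders drop and count them.
#'
#' @param smiles Character vector of SMILES strings.
#' @param fg_library,ph_library SMARTS libraries used for substructure
#'   matching (defaults: the bundled functional-group and pharmacophore
#'   libraries).
#' @param scaffold Also compute Bemis-Murcko scaffold SMILES?
#' @param cache Reuse previously parsed molecules from the in-session cache?
#' @return List of `hmol` objects (or `hmol_parse_error` records), one per
#'   input, in input order.
#' @export
parse_molecules <- function(smiles,
                            fg_library = smarts_library("functional_groups"),
                            ph_library = smarts_library("pharmacophores"),
                            scaffold = TRUE,
                            cache = TRUE) {
  stopifnot(is.character(smiles), length(smiles) >= 1, !anyNA(smiles))
  libkey <- strhash(paste(
    paste(fg_library$smarts, collapse = ";"),
    paste(ph_library$smarts, collapse = ";"), scaffold
  ))
  keys <- paste0(libkey, "|", smiles)
  out <- vector("list", length(smiles))
  if (cache) {
    hit <- vapply(keys, exists, TRUE, envir = .hypermol_cache, inherits = FALSE)
    for (i in which(hit)) out[[i]] <- get(keys[i], envir = .hypermol_cache)
  } else {
    hit <- rep(FALSE, length(smiles))
  }
  todo <- which(!hit)
  if (length(todo)) {
    response <- rdkit_call(list(
      smiles = as.list(smiles[todo]),
      patterns = list(fg = as_library_payload(fg_library),
                      ph = as_library_payload(ph_library)),
      scaffold = scaffold
    ))
    bad <- unlist(response$pattern_errors)
    if (length(bad)) {
      stop("SMARTS patterns failed to compile: ", paste(bad, collapse = ", "))
    }
    mols <- lapply(response$molecules, ingest_molecule)
    for (j in seq_along(todo)) {
      out[[todo[j]]] <- mols[[j]]
      if (cache) assign(keys[todo[j]], mols[[j]], envir = .hypermol_cache)
    }
  }
  out
}

#' Parse a single SMILES string into a molecule record
#'
#' @param smiles A SMILES string.
#' @inheritParams parse_molecules
#' @return An `hmol` object: per-atom attributes (element, atomic number,
#'   degree, formal charge, aromaticity, ring membership, attached-H count,
#'   radical electrons, Gasteiger partial charge), bonds with order class,
#'   SSSR rings, molecule-level descriptors (MW, logP, TPSA), scaffold and
#'   SMARTS match sets. Atom indices are 1-based and stable downstream.
#' @examples
#' \dontrun{
#' mol <- parse_molecule("CCO")
#' mol$atoms
#' }
#' @export
parse_molecule <- function(smiles, ...) {
  if (!is.character(smiles) || length(smiles) != 1 || !nzchar(smiles)) {
    stop("smiles must be a single non-empty string")
  }
  mol <- parse_molecules(smiles, ...)[[1]]
  if (inherits(mol, "hmol_parse_error")) {
    stop_hypermol(
      paste0("invalid molecule: ", smiles),
      "hypermol_invalid_smiles", smiles = smiles
    )
  }
  mol
}

#' @export
print.hmol <- function(x, ...) {
  cat("<molecule> ", x$smiles, "\n", sep = "")
  cat("  atoms: ", nrow(x$atoms), ", bonds: ", nrow(x$bonds),
      ", rings: ", length(x$rings), "\n", sep = "")
  cat(sprintf("  MW %.2f  logP %.2f  TPSA %.2f\n", x$mw, x$logp, x$tpsa))
  invisible(x)
}
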