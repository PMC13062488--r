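#' Load a SMARTS pattern library
#'
#' Pattern libraries are plain TSV files with columns `name`, `smarts` and
#' `tag` (a pharmacophore-class tag, or `-` for none). Two libraries ship
#' with the package: a fixed, frozen set of 69 functional-group patterns
#' spanning common functional groups, heteroaromatic rings, reactive alerts
#' and scaffold motifs, and an 18-entry pharmacophore set covering the six
#' classic classes (donor, acceptor, aromatic, hydrophobe, positive- and
#' negative-ionizable). The same libraries are applied identically to every
#' dataset; nothing is tuned per task.
#'
#' @param path Path to a TSV library file, or one of the shorthand names
#'   `"functional_groups"` / `"pharmacophores"` for the bundled files.
#' @return A data.frame of class `smarts_library` with columns
#'   `name`, `smarts`, `tag`.
#' @examples
#' lib <- smarts_library("functional_groups")
#' nrow(lib) # 69
#' @export
smarts_library <- function(path = "functional_groups") {
  if (path %in% c("functional_groups", "pharmacophores")) {
    path <- system.file("extdata", paste0(path, ".tsv"), package = "hypermol")
  }
  lib <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("name", "smarts", "tag")
  if (!all(required %in% names(lib))) {
    stop("SMARTS library must have columns: ", paste(required, collapse = ", "))
  }
  if (anyDuplicated(lib$name)) stop("duplicate pattern names in SMARTS library")
  class(lib) <- c("smarts_library", "data.frame")
  lib
}

#' Pauling electronegativity lookup table
#'
#' @return Named numeric vector mapping element symbols to Pauling
#'   electronegativities.
#' @export
electronegativity_table <- function() {
  path <- system.file("extdata", "electronegativity.tsv", package = "hypermol")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(tab$pauling, tab$element)
}

#' Metallic elements recognised as coordination centers
#'
#' @return Character vector of element symbols (alkali, alkaline-earth,
#'   transition, lanthanide and post-transition metals).
#' @export
metal_elements <- function() {
  readLines(system.file("extdata", "metals.txt", package = "hypermol"))
}
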