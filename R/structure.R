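# MolecularStructure container and validation

#' Construct a molecular structure
#'
#' A light container for one radical geometry: element symbols plus Cartesian
#' coordinates in Angstrom. Atom order is significant and preserved exactly
#' through all reads and writes, because per-atom spin and buried-volume data
#' are keyed by atom index.
#'
#' @param elements Character vector of element symbols.
#' @param coords Numeric matrix, one row per atom, columns x/y/z (Angstrom).
#' @param title Free-text title (comment line in XYZ, title line in SDF).
#' @param charge Integer molecular charge, carried as informational metadata
#'   only (it enters no computation).
#' @param id Stable identifier string; defaults to the title.
#' @return An object of class `molecular_structure`.
#' @examples
#' molecular_structure("C", matrix(0, 1, 3), title = "carbon atom")
#' @export
molecular_structure <- function(elements, coords, title = "", charge = 0L,
                                id = NULL) {
  elements <- normalize_element(as.character(elements))
  coords <- as.matrix(coords)
  if (length(elements) < 1L) {
    stop("a molecular structure needs at least one atom", call. = FALSE)
  }
  if (!is.numeric(coords) || ncol(coords) != 3L ||
      nrow(coords) != length(elements)) {
    stop("coords must be a numeric matrix with one x/y/z row per atom",
         call. = FALSE)
  }
  if (!all(is.finite(coords))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  unknown <- setdiff(unique(elements), supported_elements())
  if (length(unknown)) {
    stop("unsupported element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(
    list(elements = elements, coords = coords, title = as.character(title),
         charge = as.integer(charge),
         id = if (is.null(id)) as.character(title) else as.character(id)),
    class = "molecular_structure"
  )
}

# case-normalize element symbols: first letter upper, rest lower
normalize_element <- function(el) {
  paste0(toupper(substr(el, 1L, 1L)), tolower(substr(el, 2L, nchar(el))))
}

#' @export
print.molecular_structure <- function(x, ...) {
  cat("molecular_structure '", x$id, "': ", n_atoms(x), " atoms (",
      paste(names(sort(table(x$elements), decreasing = TRUE)), collapse = ","),
      "), charge ", x$charge, "\n", sep = "")
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure A [molecular_structure()].
#' @return Integer atom count.
#' @export
n_atoms <- function(structure) length(structure$elements)

#' Logical mask of hydrogen atoms
#' @param structure A [molecular_structure()].
#' @return Logical vector, `TRUE` where the atom is hydrogen.
#' @export
is_hydrogen <- function(structure) structure$elements == "H"

check_atom_index <- function(structure, index) {
  if (!is.numeric(index) || length(index) != 1L || is.na(index) ||
      index != as.integer(index) || index < 1L || index > n_atoms(structure)) {
    stop("atom index must be a single integer in 1..", n_atoms(structure),
         call. = FALSE)
  }
  as.integer(index)
}
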