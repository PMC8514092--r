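# van der Waals radii reference data

.BONDI_RADII <- c(
  H = 1.20, He = 1.40,
  C = 1.70, N = 1.55, O = 1.52, F = 1.47, Ne = 1.54,
  Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Ar = 1.88,
  Br = 1.85, Kr = 2.02, I = 1.98, Xe = 2.16
)

#' van der Waals radii table
#'
#' Returns a named radii table used for voxel occupancy in buried-volume
#' integration. The default (and only built-in) set is the unscaled Bondi
#' (1964) van der Waals radii, in Angstrom.
#'
#' @param name Radii set label; only `"bondi"` is built in.
#' @return An object of class `radii_table`: a named numeric vector of radii
#'   (Angstrom) with a `name` attribute.
#' @examples
#' radii_table()[["C"]]  # 1.70
#' @export
radii_table <- function(name = "bondi") {
  if (!identical(name, "bondi")) {
    stop("unknown radii set: '", name, "' (available: 'bondi')", call. = FALSE)
  }
  structure(.BONDI_RADII, name = name, class = "radii_table")
}

#' Look up a van der Waals radius
#'
#' Strict lookup of the van der Waals radius of one element. Unknown elements
#' are an explicit error, never a silent default: a missing radius would make
#' a buried-volume result quietly wrong.
#'
#' @param element Element symbol (e.g. `"C"`).
#' @param table A [radii_table()].
#' @return Radius in Angstrom.
#' @examples
#' bondi_radius("C")  # 1.70
#' @export
bondi_radius <- function(element, table = radii_table()) {
  stopifnot(is.character(element), length(element) == 1L)
  if (!element %in% names(table)) {
    stop("no van der Waals radius for element '", element, "' in radii set '",
         attr(table, "name"), "'", call. = FALSE)
  }
  unname(table[[element]])
}

#' @export
print.radii_table <- function(x, ...) {
  cat("radii_table <", attr(x, "name"), "> (", length(x), " elements, Angstrom)\n",
      sep = "")
  print(unclass(structure(as.numeric(x), names = names(x))))
  invisible(x)
}

# supported element symbols for structure validation
supported_elements <- function() names(.BONDI_RADII)
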