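# Fractional spin normalization and radical-center assignment

#' Normalize per-atom spin densities to heavy-atom fractional spins
#'
#' Converts raw signed per-atom spin densities (Mulliken-style, aligned by
#' index to the structure's atom order) into fractional spins: hydrogen atoms
#' are excluded outright, the absolute magnitudes of the heavy-atom spins are
#' summed, and each heavy atom receives its share of that sum. Heavy-atom
#' fractions therefore sum to one, and a perfectly localized radical such as
#' methyl scores exactly 1 on its carbon. The atom with the maximum fraction
#' is assigned as the radical center (ties broken toward the lowest atom
#' index, deterministically).
#'
#' Absolute values are used, so spin-polarized negative densities contribute
#' to delocalization rather than cancelling. Any per-atom signed density is
#' accepted; the population analysis and level of theory behind it are not
#' validated.
#'
#' @param structure A [molecular_structure()].
#' @param spins Numeric vector of signed spin densities, one per atom, in
#'   the structure's atom order.
#' @return An object of class `fractional_spins`: list with `fractions`
#'   (per-atom, hydrogens exactly 0), `center_index`, `max_fraction`,
#'   `center_element`.
#' @examples
#' m <- ideal_methyl()
#' fractional_spins(m$structure, m$spins)$max_fraction  # 1
#' @export
fractional_spins <- function(structure, spins) {
  stopifnot(inherits(structure, "molecular_structure"))
  spins <- as.numeric(spins)
  if (length(spins) != n_atoms(structure)) {
    stop("spin vector length (", length(spins),
         ") does not match atom count (", n_atoms(structure), ")",
         call. = FALSE)
  }
  if (!all(is.finite(spins))) stop("spin densities must be finite", call. = FALSE)
  heavy <- !is_hydrogen(structure)
  if (!any(heavy)) stop("structure has no heavy atoms", call. = FALSE)
  total <- sum(abs(spins[heavy]))
  if (total <= 0) {
    stop("all heavy-atom spin densities are zero: no radical center definable",
         call. = FALSE)
  }
  fractions <- numeric(length(spins))
  fractions[heavy] <- abs(spins[heavy]) / total
  center <- which.max(fractions)  # ties: lowest index
  out <- list(fractions = fractions,
              center_index = as.integer(center),
              max_fraction = fractions[center],
              center_element = structure$elements[center])
  class(out) <- "fractional_spins"
  out
}

#' Radical center of a fractional-spin assignment
#'
#' The radical center is the heavy atom carrying the maximum fractional
#' spin. Exact ties resolve to the lowest atom index.
#'
#' @param fractions A `fractional_spins` object.
#' @return Atom index (1-based) of the radical center.
#' @export
radical_center <- function(fractions) {
  stopifnot(inherits(fractions, "fractional_spins"))
  fractions$center_index
}

#' @export
print.fractional_spins <- function(x, ...) {
  cat("fractional_spins: center ", x$center_element, "(atom ", x$center_index,
      "), max fraction ", format(x$max_fraction, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Parse a per-atom spin-density table
#'
#' Reads a delimited two-column (`atom_index, spin`) or three-column
#' (`atom_index, element, spin`) table into a dense spin vector. The
#' delimiter (comma, tab or whitespace) is autodetected, a non-numeric
#' header line is skipped, and 0- vs 1-based indexing is either declared or
#' autodetected from the index range. When an element column is present and
#' a structure is supplied, elements are cross-checked atom by atom.
#'
#' @param source File path, connection, or character vector of lines.
#' @param n_atoms Expected number of atoms (required unless `structure` is
#'   given).
#' @param structure Optional [molecular_structure()] for length and element
#'   cross-checking.
#' @param index_base `"auto"` (default), `0`, or `1`.
#' @return Numeric spin vector in atom order.
#' @export
parse_spin_table <- function(source, n_atoms = NULL, structure = NULL,
                             index_base = "auto") {
  if (!is.null(structure)) {
    stopifnot(inherits(structure, "molecular_structure"))
    n_atoms <- length(structure$elements)
  }
  if (is.null(n_atoms)) {
    stop("either n_atoms or structure must be supplied", call. = FALSE)
  }
  lines <- read_source_lines(source)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty spin table", call. = FALSE)
  split_row <- function(x) {
    x <- trimws(x)
    if (grepl(",", x, fixed = TRUE)) trimws(strsplit(x, ",")[[1L]])
    else strsplit(x, "[\t ]+")[[1L]]
  }
  rows <- lapply(lines, split_row)
  # header detection: first field of a data row is an integer index
  is_header <- is.na(suppressWarnings(as.integer(rows[[1L]][1L])))
  if (is_header) rows <- rows[-1L]
  if (!length(rows)) stop("spin table has a header but no data", call. = FALSE)
  ncols <- unique(vapply(rows, length, integer(1)))
  if (length(ncols) != 1L || !ncols %in% c(2L, 3L)) {
    stop("spin table rows must have uniformly 2 or 3 columns", call. = FALSE)
  }
  idx <- suppressWarnings(as.integer(vapply(rows, `[[`, "", 1L)))
  val <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", ncols)))
  if (any(is.na(idx)) || any(is.na(val))) {
    stop("unparseable index or spin value in spin table", call. = FALSE)
  }
  if (anyDuplicated(idx)) {
    stop("duplicate atom index ", idx[duplicated(idx)][1L], " in spin table",
         call. = FALSE)
  }
  base <- if (identical(index_base, "auto")) {
    if (min(idx) == 0L) 0L else 1L
  } else as.integer(index_base)
  pos <- idx - base + 1L
  if (!setequal(pos, seq_len(n_atoms))) {
    stop("spin table indices (base ", base, ") are not a permutation of the ",
         n_atoms, " atom positions", call. = FALSE)
  }
  spins <- numeric(n_atoms)
  spins[pos] <- val
  if (ncols == 3L && !is.null(structure)) {
    el <- normalize_element(vapply(rows, `[[`, "", 2L))
    mism <- which(el != structure$elements[pos])
    if (length(mism)) {
      stop("element mismatch at atom ", pos[mism[1L]], ": table says '",
           el[mism[1L]], "', structure has '",
           structure$elements[pos[mism[1L]]], "'", call. = FALSE)
    }
  }
  spins
}

#' Extract Mulliken spin densities from quantum-chemistry log text
#'
#' Scans log output for a Mulliken population block carrying a spin-density
#' column (the Gaussian-style layout: a header line mentioning Mulliken and
#' spin densities, a column-label line, then one `index element charge spin`
#' row per atom). Exactly one block is expected; with several blocks (e.g.
#' logs that print populations every SCF) pass `use_last = TRUE` to take the
#' final one. A closed-shell log, whose population block has no spin column,
#' is an error.
#'
#' @param source File path, connection, or character vector of log lines.
#' @param use_last Take the last block when several are present.
#' @return Numeric spin vector in the file's atom order.
#' @export
parse_qm_mulliken_block <- function(source, use_last = FALSE) {
  lines <- read_source_lines(source)
  hdr <- grep("mulliken", lines, ignore.case = TRUE)
  hdr <- hdr[grepl("spin", lines[hdr], ignore.case = TRUE)]
  if (!length(hdr)) {
    stop("no Mulliken spin-density block found (closed-shell log?)",
         call. = FALSE)
  }
  if (length(hdr) > 1L && !use_last) {
    stop(length(hdr), " Mulliken spin blocks found; pass use_last = TRUE to ",
         "take the final one", call. = FALSE)
  }
  start <- hdr[length(hdr)]
  row_re <- "^\\s*\\d+\\s+[A-Z][a-z]?\\s+-?\\d*\\.\\d+\\s+-?\\d*\\.\\d+\\s*$"
  i <- start + 1L
  while (i <= length(lines) && !grepl(row_re, lines[i])) i <- i + 1L
  if (i > length(lines)) {
    stop("Mulliken spin block header found but no atom rows follow",
         call. = FALSE)
  }
  spins <- numeric(0)
  while (i <= length(lines) && grepl(row_re, lines[i])) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    spins <- c(spins, as.numeric(tok[4L]))
    i <- i + 1L
  }
  spins
}
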