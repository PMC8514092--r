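# XYZ reader/writer (plain dialect: count line, comment line, "El x y z" rows)

#' Read an XYZ geometry file
#'
#' Parses the plain XYZ dialect: an atom-count line, a comment line, then one
#' `element x y z` line per atom (coordinates in Angstrom). The declared atom
#' count must match the number of atom lines; mismatches, unparseable
#' coordinates and unknown elements are errors naming the offending line.
#'
#' @param source Path to a file, a connection, or a character vector of lines.
#' @param id Identifier for the structure; defaults to the comment line.
#' @return A [molecular_structure()].
#' @seealso [write_xyz()]
#' @export
read_xyz <- function(source, id = NULL) {
  lines <- read_source_lines(source)
  if (length(lines) < 3L) stop("XYZ input too short", call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L) {
    stop("XYZ line 1: expected a positive atom count, got '", lines[1L], "'",
         call. = FALSE)
  }
  title <- lines[2L]
  atom_lines <- lines[-(1:2)]
  atom_lines <- atom_lines[seq_len(min(length(atom_lines), n))]
  # drop trailing blanks only beyond the declared count
  if (length(atom_lines) < n || any(!nzchar(trimws(atom_lines)))) {
    stop("XYZ header declares ", n, " atoms but ",
         sum(nzchar(trimws(atom_lines))), " atom lines follow", call. = FALSE)
  }
  el <- character(n)
  xyz <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(atom_lines[i]), "\\s+")[[1L]]
    if (length(tok) < 4L) {
      stop("XYZ line ", i + 2L, ": expected 'element x y z', got '",
           atom_lines[i], "'", call. = FALSE)
    }
    coords <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(coords))) {
      stop("XYZ line ", i + 2L, ": unparseable coordinate in '",
           atom_lines[i], "'", call. = FALSE)
    }
    el[i] <- tok[1L]
    xyz[i, ] <- coords
  }
  molecular_structure(el, xyz, title = title, id = id)
}

#' Write an XYZ geometry file
#'
#' @param structure A [molecular_structure()].
#' @param path Output file path, or `NULL` to return the lines invisibly
#'   without writing.
#' @return The character vector of lines, invisibly.
#' @export
write_xyz <- function(structure, path = NULL) {
  lines <- c(
    as.character(n_atoms(structure)),
    structure$title,
    sprintf("%-2s %14.8f %14.8f %14.8f", structure$elements,
            structure$coords[, 1], structure$coords[, 2],
            structure$coords[, 3])
  )
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

read_source_lines <- function(source) {
  if (inherits(source, "connection")) return(readLines(source, warn = FALSE))
  if (is.character(source) && length(source) == 1L && !grepl("\n", source) &&
      file.exists(source)) {
    return(readLines(source, warn = FALSE))
  }
  if (is.character(source)) {
    if (!any(grepl("\n", source, fixed = TRUE))) return(source)
    return(strsplit(paste(source, collapse = "\n"), "\n", fixed = TRUE)[[1L]])
  }
  stop("source must be a file path, connection, or character vector",
       call. = FALSE)
}
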