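# SDF V2000 reader (via ChemmineR) and writer

#' Read a (multi-record) SDF V2000 file
#'
#' Parsing is delegated to \pkg{ChemmineR}. One `molecular_structure` is
#' returned per record; the atom order of each structure equals the SDF
#' atom-block order, which is the key for per-atom spin and buried-volume
#' columns in deposit-style CSV tables. Bond blocks are parsed by ChemmineR
#' but connectivity is not used by any computation here (buried volume is
#' purely distance-based); bonds are retained only inside the ChemmineR
#' object and dropped from the returned structures.
#'
#' @param source Path to an SDF file, or a character vector of SDF lines.
#' @return A list of [molecular_structure()], ids taken from the title lines
#'   (falling back to `mol_<i>` for blank titles).
#' @seealso [write_sdf()]
#' @export
read_sdf <- function(source) {
  lines <- read_source_lines(source)
  path <- tempfile(fileext = ".sdf")
  on.exit(unlink(path), add = TRUE)
  writeLines(lines, path)
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(path, skipErrors = FALSE)),
    error = function(e) stop("SDF parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (length(sdfset) == 0L) stop("SDF input contains no records", call. = FALSE)
  titles <- ChemmineR::sdfid(sdfset)
  out <- vector("list", length(sdfset))
  for (i in seq_along(sdfset)) {
    ab <- ChemmineR::atomblock(sdfset[[i]])
    if (!is.matrix(ab) || nrow(ab) < 1L || ncol(ab) < 3L ||
        anyNA(ab[, 1:3])) {
      stop("SDF parse error in record ", i,
           " (malformed counts line or missing 'M  END')", call. = FALSE)
    }
    el <- sub("_.*$", "", rownames(ab))
    title <- titles[i]
    if (is.na(title) || !nzchar(trimws(title))) title <- paste0("mol_", i)
    out[[i]] <- molecular_structure(el, ab[, 1:3, drop = FALSE],
                                    title = trimws(title))
  }
  out
}

#' Write structures to an SDF V2000 file
#'
#' Emits minimal valid V2000 records (atom block only, no bonds: connectivity
#' is not tracked by `molecular_structure`). Atom order is written exactly as
#' stored so that index-keyed per-atom data stay aligned across round-trips.
#'
#' @param structures A [molecular_structure()] or list of them.
#' @param path Output file path, or `NULL` to return lines invisibly.
#' @return The character vector of lines, invisibly.
#' @export
write_sdf <- function(structures, path = NULL) {
  if (inherits(structures, "molecular_structure")) structures <- list(structures)
  blocks <- lapply(structures, function(s) {
    n <- n_atoms(s)
    c(
      if (nzchar(s$id)) s$id else s$title,
      "  radstab",
      "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, 0L),
      # 6 decimals (vs the classic 4) so coordinates round-trip to < 1e-6 A
      sprintf("%12.6f%12.6f%12.6f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              s$coords[, 1], s$coords[, 2], s$coords[, 3], s$elements),
      "M  END",
      "$$$$"
    )
  })
  lines <- unlist(blocks, use.names = FALSE)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
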