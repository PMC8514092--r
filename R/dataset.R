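# Deposit-style dataset loading and summary analytics

#' Load a per-atom radical descriptor dataset
#'
#' Reads a deposit-style CSV in which each row is one atom of one radical:
#' required columns `molecule_id`, `atom_index` (0-based, the canonical atom
#' order of the corresponding SDF record), `element`, `fractional_spin`,
#' `percent_buried`; optional molecule-level columns `bde`, `rse`
#' (kcal/mol, consumed as annotation, never computed here) and
#' `is_known_stable`. Per-molecule center and maximum-fraction fields are
#' recomputed from the per-atom data; if the CSV also carries `max_fraction`
#' or `center_index` columns they are cross-checked and a mismatch is an
#' error. When an SDF stream accompanies the CSV, every molecule is joined
#' against its geometry record and atom counts and elements must agree index
#' by index.
#'
#' @param csv File path, connection, or character lines of the CSV.
#' @param sdf Optional SDF source (path or lines) for the join check.
#' @param config A [score_config()] used for the recomputed score column.
#' @return An object of class `radical_dataset`: list with `molecules` (one
#'   row per radical: `id`, `n_atoms`, `center_index` (1-based),
#'   `center_element`, `max_fraction`, `percent_buried`, `rss`, plus any
#'   molecule-level optional columns) and `atoms` (the per-atom table).
#' @export
load_dataset <- function(csv, sdf = NULL, config = score_config()) {
  lines <- read_source_lines(csv)
  atoms <- utils::read.csv(text = paste(lines, collapse = "\n"),
                           stringsAsFactors = FALSE, comment.char = "#")
  required <- c("molecule_id", "atom_index", "element", "fractional_spin",
                "percent_buried")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    stop("dataset CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  atoms$element <- normalize_element(atoms$element)
  structures <- NULL
  if (!is.null(sdf)) {
    sl <- read_sdf(sdf)
    structures <- stats::setNames(sl, vapply(sl, `[[`, "", "id"))
  }
  by_mol <- split(atoms, atoms$molecule_id)
  rows <- lapply(names(by_mol), function(mid) {
    a <- by_mol[[mid]]
    a <- a[order(a$atom_index), , drop = FALSE]
    n <- nrow(a)
    if (!identical(as.integer(a$atom_index), 0:(n - 1L))) {
      stop("molecule '", mid, "': atom_index is not a permutation of 0..",
           n - 1L, call. = FALSE)
    }
    if (!is.null(structures)) {
      s <- structures[[mid]]
      if (is.null(s)) {
        stop("molecule '", mid, "' has no matching SDF record", call. = FALSE)
      }
      if (n_atoms(s) != n || !identical(s$elements, a$element)) {
        stop("molecule '", mid, "': CSV atoms do not match the SDF record ",
             "(count or element at some index)", call. = FALSE)
      }
    }
    heavy <- a$element != "H"
    if (!any(heavy) || all(a$fractional_spin[heavy] == 0)) {
      stop("molecule '", mid, "': no heavy atom carries spin", call. = FALSE)
    }
    frac <- ifelse(heavy, a$fractional_spin, 0)
    center <- which.max(frac)
    if ("max_fraction" %in% names(a)) {
      claimed <- a$max_fraction[1L]
      if (is.finite(claimed) && abs(claimed - frac[center]) > 1e-6) {
        stop("molecule '", mid, "': stored max_fraction ", claimed,
             " disagrees with recomputed ", frac[center], call. = FALSE)
      }
    }
    if ("center_index" %in% names(a)) {
      claimed <- as.integer(a$center_index[1L])
      if (!is.na(claimed) && claimed != center - 1L) {
        stop("molecule '", mid, "': stored center_index ", claimed,
             " disagrees with recomputed ", center - 1L, call. = FALSE)
      }
    }
    row <- data.frame(
      id = mid, n_atoms = n, center_index = center,
      center_element = a$element[center],
      max_fraction = frac[center],
      percent_buried = a$percent_buried[center],
      stringsAsFactors = FALSE
    )
    for (opt in c("bde", "rse", "is_known_stable")) {
      if (opt %in% names(a)) row[[opt]] <- a[[opt]][1L]
    }
    row
  })
  molecules <- do.call(rbind, rows)
  rownames(molecules) <- NULL
  molecules$rss <- radical_stability_score(molecules$percent_buried,
                                           molecules$max_fraction, config)
  out <- list(molecules = molecules, atoms = atoms)
  class(out) <- "radical_dataset"
  out
}

#' @export
print.radical_dataset <- function(x, ...) {
  cat("radical_dataset: ", nrow(x$molecules), " molecules, ",
      nrow(x$atoms), " atom rows\n", sep = "")
  invisible(x)
}

#' Radical counts by center element
#'
#' @param records A `radical_dataset` or a stability-record data.frame with
#'   a `center_element` column.
#' @return Named integer vector of counts; the sum equals the number of
#'   records.
#' @export
element_counts <- function(records) {
  if (inherits(records, "radical_dataset")) records <- records$molecules
  stopifnot(is.data.frame(records), "center_element" %in% names(records))
  tab <- table(records$center_element)
  stats::setNames(as.integer(tab), names(tab))
}

#' Percentile rank within a reference distribution
#'
#' `100 * (#values <= x) / N`: the weak-inequality convention, under which a
#' value equal to the distribution maximum ranks 100. Monotone
#' non-decreasing in `x`.
#'
#' @param values Nonempty numeric reference distribution.
#' @param x Query value(s).
#' @return Percentile(s) in `[0, 100]`.
#' @examples
#' percentile_rank(1:100, 97)  # 97
#' @export
percentile_rank <- function(values, x) {
  values <- as.numeric(values)
  if (!length(values)) stop("empty reference distribution", call. = FALSE)
  vapply(as.numeric(x), function(xi) 100 * mean(values <= xi), numeric(1))
}

#' Enrichment of known stable radicals in a score distribution
#'
#' Computes, for each known-stable radical's score, its percentile rank in
#' the full dataset's score distribution, and returns the minimum — the
#' worst-ranked stable radical. A high minimum (e.g. at or above the 97th
#' percentile) means the score concentrates the empirically stable species
#' in its upper tail. The statistic is invariant under any order-preserving
#' transform applied to both inputs.
#'
#' @param dataset_rss Scores of the full dataset (nonempty).
#' @param stable_rss Scores of the known stable radicals (nonempty).
#' @return Minimum percentile rank over the stable set.
#' @export
stable_enrichment <- function(dataset_rss, stable_rss) {
  if (!length(dataset_rss) || !length(stable_rss)) {
    stop("dataset_rss and stable_rss must both be nonempty", call. = FALSE)
  }
  min(percentile_rank(dataset_rss, stable_rss))
}

#' Squared Pearson correlation
#'
#' @param x,y Numeric vectors of equal length (>= 3), each with nonzero
#'   variance.
#' @return R-squared in `[0, 1]`.
#' @export
r_squared <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3L) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: zero variance", call. = FALSE)
  }
  stats::cor(x, y)^2
}

#' Sphere-radius robustness of the buried-volume descriptor
#'
#' Computes percent buried volume for each structure (at its given center)
#' across several sphere radii and returns the matrix of pairwise R-squared
#' values between the resulting descriptor vectors. High off-diagonal values
#' mean the steric ranking is insensitive to the sphere-radius choice.
#'
#' @param structures List of [molecular_structure()] (length >= 3).
#' @param centers Integer vector of center atom indices, one per structure.
#' @param radii Sphere radii to scan (Angstrom), ascending.
#' @param grid Base [grid_spec()] supplying spacing/radii-set/occupancy
#'   conventions.
#' @return Symmetric matrix of R-squared values with unit diagonal,
#'   dimnames = radii. The per-radius descriptor vectors are attached as
#'   attribute `"percents"`.
#' @export
radius_robustness <- function(structures, centers,
                              radii = c(2.5, 3.0, 3.5, 4.0),
                              grid = grid_spec()) {
  stopifnot(is.list(structures), length(structures) >= 3L,
            length(centers) == length(structures))
  percents <- sapply(seq_along(radii), function(k) {
    g <- grid_spec(sphere_radius = radii[k], spacing = grid$spacing,
                   radii = grid$radii,
                   include_center_atom = grid$include_center_atom,
                   include_hydrogens = grid$include_hydrogens)
    vapply(seq_along(structures), function(i) {
      buried_volume(structures[[i]], centers[i], g)$percent_buried
    }, numeric(1))
  })
  colnames(percents) <- format(radii)
  m <- diag(length(radii))
  for (a in seq_along(radii)) {
    for (b in seq_along(radii)) {
      if (a < b) m[a, b] <- m[b, a] <- r_squared(percents[, a], percents[, b])
    }
  }
  dimnames(m) <- list(format(radii), format(radii))
  attr(m, "percents") <- percents
  m
}
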