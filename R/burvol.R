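# Percent buried volume by voxel integration on a Cartesian grid

#' Grid settings for buried-volume integration
#'
#' Defaults follow the descriptor's standard convention: a 3.5 Angstrom
#' sphere sampled on a 0.05 Angstrom Cartesian grid with unscaled Bondi van
#' der Waals radii, every atom of the molecule — the central atom and all
#' hydrogens included — contributing occupancy. Excluding the center
#' (`include_center_atom = FALSE`) recovers the ligand-style convention
#' inherited from organometallic percent-buried-volume analysis; it is
#' exposed for sensitivity studies only, as is `include_hydrogens`.
#'
#' @param sphere_radius Sphere radius, Angstrom (> 0).
#' @param spacing Voxel edge length, Angstrom; must satisfy
#'   `0 < spacing <= sphere_radius / 10`.
#' @param radii A [radii_table()].
#' @param include_center_atom Does the center atom's own van der Waals
#'   sphere occupy voxels?
#' @param include_hydrogens Do hydrogen atoms occupy voxels?
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(sphere_radius = 3.5, spacing = 0.05,
                      radii = radii_table(), include_center_atom = TRUE,
                      include_hydrogens = TRUE) {
  stopifnot(is.numeric(sphere_radius), length(sphere_radius) == 1L,
            is.numeric(spacing), length(spacing) == 1L,
            inherits(radii, "radii_table"))
  if (!is.finite(sphere_radius) || sphere_radius <= 0) {
    stop("sphere_radius must be positive", call. = FALSE)
  }
  if (!is.finite(spacing) || spacing <= 0 || spacing > sphere_radius / 10) {
    stop("spacing must satisfy 0 < spacing <= sphere_radius/10", call. = FALSE)
  }
  structure(
    list(sphere_radius = sphere_radius, spacing = spacing, radii = radii,
         include_center_atom = isTRUE(include_center_atom),
         include_hydrogens = isTRUE(include_hydrogens)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("grid_spec: sphere ", x$sphere_radius, " A, spacing ", x$spacing,
      " A, radii '", attr(x$radii, "name"), "', center ",
      if (x$include_center_atom) "included" else "excluded", ", hydrogens ",
      if (x$include_hydrogens) "included" else "excluded", "\n", sep = "")
  invisible(x)
}

# voxel centers inside the sphere, as offsets from the center atom:
# axis-aligned grid anchored at the center atom's position
sphere_grid_points <- function(sphere_radius, spacing) {
  n <- floor(sphere_radius / spacing)
  g <- spacing * seq.int(-n, n)
  gx <- rep(g, times = (2L * n + 1L)^2)
  gy <- rep(rep(g, each = 2L * n + 1L), times = 2L * n + 1L)
  gz <- rep(g, each = (2L * n + 1L)^2)
  keep <- gx * gx + gy * gy + gz * gz <= sphere_radius^2
  cbind(x = gx[keep], y = gy[keep], z = gz[keep])
}

#' Percent buried volume around one atom
#'
#' Quantifies steric crowding as the occupied percentage of a sphere of
#' fixed radius centered on the chosen atom. The sphere is discretized into
#' cubic voxels on an axis-aligned grid anchored at the center atom's
#' position; a voxel belongs to the sphere if its center lies within
#' `sphere_radius` of the center atom, and is occupied if its center lies
#' within the van der Waals radius of any included atom. No partial-volume
#' weighting is applied: at the default 0.05 Angstrom spacing the residual
#' discretization error is below 0.2 percentage points against the analytic
#' single-sphere value. Atoms whose van der Waals sphere cannot reach the
#' sampling sphere are skipped (a pure optimization with a bit-identical
#' result).
#'
#' @param structure A [molecular_structure()].
#' @param center_index Atom index (1-based) of the sphere center, typically
#'   the radical center from [fractional_spins()].
#' @param grid A [grid_spec()].
#' @return An object of class `buried_volume_result`: list with
#'   `percent_buried` (0-100), `occupied_voxels`, `total_voxels`,
#'   `center_index` and `grid`.
#' @examples
#' m <- ideal_methyl()
#' buried_volume(m$structure, 1L)$percent_buried  # about 14.6
#' @export
buried_volume <- function(structure, center_index, grid = grid_spec()) {
  stopifnot(inherits(structure, "molecular_structure"),
            inherits(grid, "grid_spec"))
  center_index <- check_atom_index(structure, center_index)
  vdw <- vapply(structure$elements, bondi_radius, numeric(1),
                table = grid$radii)
  pts <- sphere_grid_points(grid$sphere_radius, grid$spacing)
  total <- nrow(pts)
  occupied <- occupy_voxels(pts, structure, center_index, vdw, grid)
  new_buried_volume_result(occupied, total, center_index, grid)
}

new_buried_volume_result <- function(occupied, total, center_index, grid) {
  out <- list(percent_buried = 100 * occupied / total,
              occupied_voxels = occupied, total_voxels = total,
              center_index = center_index, grid = grid)
  class(out) <- "buried_volume_result"
  out
}

occupy_voxels <- function(pts, structure, center_index, vdw, grid) {
  c0 <- structure$coords[center_index, ]
  occ <- logical(nrow(pts))
  for (i in seq_len(n_atoms(structure))) {
    if (i == center_index) {
      if (!grid$include_center_atom) next
    } else if (!grid$include_hydrogens && structure$elements[i] == "H") {
      next
    }
    d <- structure$coords[i, ] - c0
    # reach filter: atom sphere cannot intersect the sampling sphere
    if (sqrt(sum(d * d)) - vdw[i] > grid$sphere_radius) next
    r2 <- vdw[i]^2
    dx <- pts[, 1L] - d[1L]
    dy <- pts[, 2L] - d[2L]
    dz <- pts[, 3L] - d[3L]
    occ <- occ | (dx * dx + dy * dy + dz * dz <= r2)
  }
  sum(occ)
}

#' @export
print.buried_volume_result <- function(x, ...) {
  cat(sprintf("buried volume: %.2f%% (%d / %d voxels), center atom %d\n",
              x$percent_buried, x$occupied_voxels, x$total_voxels,
              x$center_index))
  invisible(x)
}

#' Buried volume around every atom
#'
#' Applies [buried_volume()] with each atom in turn as the sphere center.
#' The shared sphere voxelization is computed once.
#'
#' @inheritParams buried_volume
#' @return List of `buried_volume_result`, one per atom, in atom order.
#' @export
buried_volume_all_atoms <- function(structure, grid = grid_spec()) {
  stopifnot(inherits(structure, "molecular_structure"),
            inherits(grid, "grid_spec"))
  vdw <- vapply(structure$elements, bondi_radius, numeric(1),
                table = grid$radii)
  pts <- sphere_grid_points(grid$sphere_radius, grid$spacing)
  total <- nrow(pts)
  lapply(seq_len(n_atoms(structure)), function(k) {
    occupied <- occupy_voxels(pts, structure, k, vdw, grid)
    new_buried_volume_result(occupied, total, k, grid)
  })
}

#' Buried volume across a range of sphere radii
#'
#' Recomputes the percent buried volume at each requested sphere radius with
#' all other grid settings held fixed — the robustness scan used to confirm
#' that descriptor values at nearby radii are highly correlated.
#'
#' @inheritParams buried_volume
#' @param radii_list Numeric vector of sphere radii, positive and ascending.
#' @return A data.frame with columns `radius` and `percent_buried`.
#' @export
radius_scan <- function(structure, center_index, radii_list,
                        grid = grid_spec()) {
  radii_list <- as.numeric(radii_list)
  if (!length(radii_list)) {
    return(data.frame(radius = numeric(0), percent_buried = numeric(0)))
  }
  if (any(!is.finite(radii_list)) || any(radii_list <= 0) ||
      is.unsorted(radii_list, strictly = TRUE)) {
    stop("radii_list must be positive and strictly ascending", call. = FALSE)
  }
  percent <- vapply(radii_list, function(r) {
    g <- grid_spec(sphere_radius = r, spacing = grid$spacing,
                   radii = grid$radii,
                   include_center_atom = grid$include_center_atom,
                   include_hydrogens = grid$include_hydrogens)
    buried_volume(structure, center_index, g)$percent_buried
  }, numeric(1))
  data.frame(radius = radii_list, percent_buried = percent)
}
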