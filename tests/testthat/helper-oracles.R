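# Independent oracles and small builders shared across the suite.

# volume of a sphere of radius r
sphere_vol <- function(r) 4 / 3 * pi * r^3

# volume of the lens (intersection) of two spheres of radii r1, r2 whose
# centers are d apart (standard closed form; valid for overlapping,
# non-nested spheres)
lens_vol <- function(r1, r2, d) {
  pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * r2 - 3 * r2^2 + 2 * d * r1 + 6 * r1 * r2 - 3 * r1^2) /
    (12 * d)
}

# analytic percent buried volume of idealized planar CH3, sphere radius R:
# every pairwise H-H intersection lies entirely inside the C sphere, so by
# inclusion-exclusion the union reduces to V(C) + sum_i [V(H_i) - V(C^H_i)];
# all four vdW spheres lie fully inside the default 3.5 A sampling sphere.
methyl_analytic_percent <- function(ch_bond = 1.08, r_c = 1.70, r_h = 1.20,
                                    sphere_radius = 3.5) {
  stopifnot(ch_bond + r_h <= sphere_radius, r_c <= sphere_radius)
  union_vol <- sphere_vol(r_c) + 3 * (sphere_vol(r_h) - lens_vol(r_c, r_h, ch_bond))
  100 * union_vol / sphere_vol(sphere_radius)
}

# Monte-Carlo percent buried volume: uniform points in the sampling sphere,
# fraction falling inside any vdW sphere. Returns estimate and standard error.
mc_buried_volume <- function(structure, center_index, sphere_radius = 3.5,
                             n_points = 1e6, seed = 7L) {
  set.seed(seed)
  pts <- matrix(stats::runif(3 * n_points * 2, -sphere_radius, sphere_radius),
                ncol = 3)
  pts <- pts[rowSums(pts^2) <= sphere_radius^2, , drop = FALSE]
  pts <- pts[seq_len(min(nrow(pts), n_points)), , drop = FALSE]
  c0 <- structure$coords[center_index, ]
  occ <- rep(FALSE, nrow(pts))
  for (i in seq_len(n_atoms(structure))) {
    r <- bondi_radius(structure$elements[i])
    d <- structure$coords[i, ] - c0
    occ <- occ | (rowSums(sweep(pts, 2, d)^2) <= r^2)
  }
  p <- mean(occ)
  list(percent = 100 * p,
       se = 100 * sqrt(p * (1 - p) / nrow(pts)))
}

# O(n^2) brute-force Pareto dominance oracle: maximize percent_buried,
# minimize max_fraction
brute_force_front <- function(records) {
  v <- records$percent_buried
  s <- records$max_fraction
  n <- length(v)
  vapply(seq_len(n), function(a) {
    dominated <- v >= v[a] & s <= s[a] & (v > v[a] | s < s[a])
    !any(dominated)
  }, logical(1))
}

# random stability records with deliberate coordinate ties
random_records <- function(n, seed, tie_fraction = 0.1) {
  set.seed(seed)
  v <- round(runif(n, 10, 70), 1)   # rounding forces ties
  s <- round(runif(n, 0.15, 1), 2)
  k <- floor(n * tie_fraction)
  if (k >= 1 && n >= 2 * k) {       # exact duplicates in both coordinates
    v[seq_len(k)] <- v[n - seq_len(k) + 1]
    s[seq_len(k)] <- s[n - seq_len(k) + 1]
  }
  stability_record(sprintf("r%04d", seq_len(n)), s, v,
                   sample(c("C", "N", "O", "S"), n, replace = TRUE))
}

# rotate + translate a structure rigidly
rigid_transform <- function(structure, angles, shift) {
  cs <- cos(angles); sn <- sin(angles)
  Rx <- rbind(c(1, 0, 0), c(0, cs[1], -sn[1]), c(0, sn[1], cs[1]))
  Ry <- rbind(c(cs[2], 0, sn[2]), c(0, 1, 0), c(-sn[2], 0, cs[2]))
  Rz <- rbind(c(cs[3], -sn[3], 0), c(sn[3], cs[3], 0), c(0, 0, 1))
  coords <- structure$coords %*% t(Rx %*% Ry %*% Rz)
  coords <- sweep(coords, 2, shift, `+`)
  molecular_structure(structure$elements, coords, title = structure$title,
                      id = structure$id)
}

# Gaussian-style log text with one or two Mulliken spin blocks
mulliken_log <- function(spins_list, elements) {
  blocks <- lapply(spins_list, function(sp) {
    c(" Mulliken charges and spin densities:",
      "               1          2",
      sprintf("  %4d  %-2s  %9.6f  %9.6f", seq_along(sp), elements,
              runif(length(sp), -0.3, 0.3), sp),
      " Sum of Mulliken charges =   0.00000")
  })
  c(" Entering Link 1", unlist(blocks), " Normal termination")
}

closed_shell_log <- function(elements) {
  c(" Entering Link 1",
    " Mulliken charges:",
    "               1",
    sprintf("  %4d  %-2s  %9.6f", seq_along(elements), elements,
            runif(length(elements), -0.3, 0.3)),
    " Normal termination")
}
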