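single_atom <- function(el = "C") {
  molecular_structure(el, matrix(0, 1, 3), id = paste0("lone_", el))
}

test_that("single-atom buried volume matches the closed-form volume ratio", {
  bv <- buried_volume(single_atom("C"), 1L)$percent_buried
  expect_lt(abs(bv - 100 * (1.70 / 3.5)^3), 0.2)
  expect_equal(buried_volume(single_atom("C"), 1L)$center_index, 1L)
})

test_that("an atom sphere covering the whole sampling sphere gives 100%", {
  g <- grid_spec(sphere_radius = 1.5, spacing = 0.05)
  expect_equal(buried_volume(single_atom("C"), 1L, g)$percent_buried, 100)
})

test_that("grid error decreases strictly with spacing (convergence)", {
  analytic <- 100 * (1.70 / 3.5)^3
  errs <- vapply(c(0.2, 0.1, 0.05), function(sp) {
    g <- grid_spec(spacing = sp)
    abs(buried_volume(single_atom("C"), 1L, g)$percent_buried - analytic)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.2)
})

test_that("methyl buried volume matches the union-of-spheres oracle", {
  m <- ideal_methyl()
  bv <- buried_volume(m$structure, 1L)$percent_buried
  expect_gte(bv, 13)
  expect_lt(abs(bv - methyl_analytic_percent()), 0.2)
})

test_that("grid result agrees with a Monte-Carlo estimate within 3 sigma", {
  m <- ideal_methyl()
  for (case in list(list(s = single_atom("C"), i = 1L),
                    list(s = m$structure, i = 1L))) {
    grid_val <- buried_volume(case$s, case$i)$percent_buried
    mc <- mc_buried_volume(case$s, case$i)
    expect_lt(abs(grid_val - mc$percent), 3 * mc$se + 0.05)
  }
})

test_that("per-atom sweep equals single-center calls", {
  m <- ideal_methyl()
  all_bv <- buried_volume_all_atoms(m$structure)
  expect_length(all_bv, 4L)
  for (k in 1:4) {
    expect_identical(all_bv[[k]]$occupied_voxels,
                     buried_volume(m$structure, k)$occupied_voxels)
  }
  # methyl is small enough that the whole vdW union sits inside every
  # atom's sampling sphere, so all four percents agree up to grid jitter
  percents <- vapply(all_bv, `[[`, numeric(1), "percent_buried")
  expect_lt(diff(range(percents)), 0.15)
  expect_length(buried_volume_all_atoms(single_atom("O")), 1L)
})

test_that("a crowded center is more buried than a peripheral hydrogen", {
  tb <- ideal_tert_butyl()$structure
  g <- grid_spec(spacing = 0.1)
  all_bv <- buried_volume_all_atoms(tb, g)
  central <- all_bv[[1]]$percent_buried
  h_vals <- vapply(all_bv[which(is_hydrogen(tb))], `[[`, numeric(1),
                   "percent_buried")
  expect_true(all(central > h_vals))
})

test_that("adding an atom never decreases the buried volume", {
  g <- grid_spec(spacing = 0.1)
  m <- ideal_methyl()$structure
  set.seed(5)
  for (rep in 1:5) {
    base <- buried_volume(m, 1L, g)$occupied_voxels
    extra <- molecular_structure(
      c(m$elements, "H"),
      rbind(m$coords, runif(3, -2.5, 2.5)), id = "methyl+H")
    expect_gte(buried_volume(extra, 1L, g)$occupied_voxels, base)
  }
})

test_that("rigid motions change the percent by at most the jitter bound", {
  m <- ideal_methyl()$structure
  base <- buried_volume(m, 1L)$percent_buried
  set.seed(42)
  for (rep in 1:4) {
    moved <- rigid_transform(m, runif(3, 0, 2 * pi), runif(3, -10, 10))
    expect_lt(abs(buried_volume(moved, 1L)$percent_buried - base), 0.15)
  }
})

test_that("occupancy conventions and bounds behave as declared", {
  m <- ideal_methyl()$structure
  # center excluded: only the three H spheres occupy
  no_center <- buried_volume(m, 1L, grid_spec(include_center_atom = FALSE))
  with_center <- buried_volume(m, 1L)
  expect_lt(no_center$percent_buried, with_center$percent_buried)
  expect_gt(no_center$percent_buried, 0)
  # hydrogens excluded: reduces to the lone-carbon value
  no_h <- buried_volume(m, 1L, grid_spec(include_hydrogens = FALSE))
  expect_equal(no_h$occupied_voxels,
               buried_volume(single_atom("C"), 1L)$occupied_voxels)
  expect_equal(with_center$percent_buried,
               100 * with_center$occupied_voxels / with_center$total_voxels)
})

test_that("radius_scan reproduces closed forms and respects emptiness", {
  sc <- radius_scan(single_atom("C"), 1L, c(2.5, 3.5))
  expect_equal(sc$radius, c(2.5, 3.5))
  expect_lt(abs(sc$percent_buried[1] - 100 * (1.7 / 2.5)^3), 0.2)
  expect_lt(abs(sc$percent_buried[2] - 100 * (1.7 / 3.5)^3), 0.2)
  # once the sphere contains all vdW spheres, percent is decreasing in radius
  m <- ideal_methyl()$structure
  sm <- radius_scan(m, 1L, c(2.5, 3.0, 3.5, 4.0), grid_spec(spacing = 0.1))
  expect_true(all(diff(sm$percent_buried) < 0))
  empty <- radius_scan(single_atom("C"), 1L, numeric(0))
  expect_equal(nrow(empty), 0L)
  expect_error(radius_scan(single_atom("C"), 1L, c(3.5, 2.5)), "ascending")
})

test_that("grid specs and center indices are validated", {
  expect_error(grid_spec(sphere_radius = -1), "positive")
  expect_error(grid_spec(spacing = 0.5), "spacing")
  expect_error(grid_spec(spacing = 0), "spacing")
  expect_error(buried_volume(single_atom("C"), 2L), "atom index")
  expect_error(buried_volume(single_atom("C"), 0L), "atom index")
})
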