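two_mol_csv <- function() {
  c("molecule_id,atom_index,element,fractional_spin,percent_buried",
    "m1,0,C,0.8,30", "m1,1,N,0.2,25", "m1,2,H,0,5",
    "m2,0,O,0.45,50", "m2,1,C,0.55,45", "m2,2,H,0,4", "m2,3,H,0,4")
}

test_that("load_dataset groups per molecule and recomputes centers", {
  ds <- load_dataset(two_mol_csv())
  expect_equal(nrow(ds$molecules), 2L)
  m1 <- ds$molecules[ds$molecules$id == "m1", ]
  m2 <- ds$molecules[ds$molecules$id == "m2", ]
  expect_equal(m1$center_element, "C")
  expect_equal(m1$max_fraction, 0.8)
  expect_equal(m1$percent_buried, 30)
  expect_equal(m2$center_element, "C")   # C 0.55 beats O 0.45
  expect_equal(m2$center_index, 2L)
  expect_equal(m2$rss, 45 + 50 * (1 - 0.55))
})

test_that("index gaps, schema holes, and stored-field mismatches error", {
  bad <- c("molecule_id,atom_index,element,fractional_spin,percent_buried",
           "m1,0,C,0.8,30", "m1,1,N,0.2,25", "m1,3,H,0,5")
  expect_error(load_dataset(bad), "'m1'.*not a permutation")
  expect_error(load_dataset(c("molecule_id,atom_index,element,fractional_spin",
                              "m1,0,C,0.8")),
               "missing required column.*percent_buried")
  clash <- c(paste0("molecule_id,atom_index,element,fractional_spin,",
                    "percent_buried,max_fraction"),
             "m1,0,C,0.8,30,0.7", "m1,1,N,0.2,25,0.7")
  expect_error(load_dataset(clash), "disagrees")
})

test_that("the SDF join is exact and orphans are fatal", {
  structures <- list(
    molecular_structure(c("C", "N", "H"),
                        rbind(c(0, 0, 0), c(1.4, 0, 0), c(-1.1, 0, 0)),
                        id = "m1"),
    molecular_structure(c("O", "C", "H", "H"),
                        rbind(c(0, 0, 0), c(1.4, 0, 0),
                              c(2.0, 0.9, 0), c(2.0, -0.9, 0)),
                        id = "m2"))
  structures[[1]]$title <- "m1"; structures[[2]]$title <- "m2"
  ds <- load_dataset(two_mol_csv(), sdf = write_sdf(structures))
  expect_equal(nrow(ds$molecules), 2L)
  # element clash at one index
  swapped <- structures
  swapped[[1]]$elements <- c("N", "C", "H")
  expect_error(load_dataset(two_mol_csv(), sdf = write_sdf(swapped)),
               "do not match")
})

test_that("element counts are exact and conserve the record total", {
  d <- synthetic_dataset(200, seed = 4)
  counts <- element_counts(d$molecules)
  expect_equal(sum(counts), 200L)
  expect_equal(unname(counts["C"]),
               sum(d$molecules$center_element == "C"))
  ds <- load_dataset(write_dataset_csv(d))
  expect_equal(element_counts(ds), counts)
})

test_that("percentile ranks use the weak-inequality convention", {
  expect_equal(percentile_rank(1:100, 97), 97)
  expect_equal(percentile_rank(1:100, 100), 100)
  expect_equal(percentile_rank(1:100, 0.5), 0)   # below the minimum
  expect_equal(percentile_rank(c(5, 5, 5, 9), 5), 75)
  expect_error(percentile_rank(numeric(0), 1), "empty")
  # sort-based oracle on random data + monotonicity in x
  set.seed(8)
  vals <- rnorm(500)
  qs <- sort(rnorm(20))
  oracle <- vapply(qs, function(q) 100 * sum(sort(vals) <= q) / 500,
                   numeric(1))
  got <- percentile_rank(vals, qs)
  expect_equal(got, oracle)
  expect_true(all(diff(got) >= 0))
})

test_that("stable-set enrichment is the minimum stable percentile", {
  scores <- 1:100
  expect_gte(stable_enrichment(scores, c(98, 99, 100)), 97)
  expect_lte(stable_enrichment(scores, c(1, 99)), 1)
  # invariance under an order-preserving transform of both inputs
  expect_equal(stable_enrichment(exp(scores / 10), exp(c(98, 99, 100) / 10)),
               stable_enrichment(scores, c(98, 99, 100)))
  expect_error(stable_enrichment(numeric(0), 1), "nonempty")
})

test_that("r_squared matches the direct covariance formula", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(r_squared(x, 2 * x + 1), 1.0)
  expect_equal(r_squared(c(-1, 0, 1), c(1, -2, 1)), 0.0)  # orthogonal
  set.seed(13)
  a <- rnorm(50); b <- 0.4 * a + rnorm(50)
  direct <- (sum((a - mean(a)) * (b - mean(b))))^2 /
    (sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(r_squared(a, b), direct, tolerance = 1e-12)
  expect_error(r_squared(a, rep(1, 50)), "zero variance")
  expect_error(r_squared(1:2, 1:2), "length")
})

test_that("buried volumes at nearby sphere radii are highly correlated", {
  lib <- fixture_library()[c("methyl", "ethyl", "allyl", "tert_butyl")]
  structures <- lapply(lib, `[[`, "structure")
  centers <- vapply(lib, function(f)
    radical_center(fractional_spins(f$structure, f$spins)), integer(1))
  m <- radius_robustness(structures, centers, grid = grid_spec(spacing = 0.1))
  expect_equal(dim(m), c(4L, 4L))
  expect_equal(unname(diag(m)), rep(1, 4))
  expect_equal(m, t(m), ignore_attr = TRUE)
  expect_true(all(m[upper.tri(m)] > 0.9))
  # replicating one structure makes a descriptor vector constant -> error
  same <- structures[c(1, 1, 1)]
  expect_error(radius_robustness(same, rep(1L, 3),
                                 grid = grid_spec(spacing = 0.1)),
               "zero variance")
})
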