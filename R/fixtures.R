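# Idealized geometries, synthetic spin vectors and a synthetic dataset
# generator, so every computation is testable without external data.
#
# Spin vectors here are hand-designed to be plausible (polarization signs,
# near-degeneracy for the nitroxide), not DFT-accurate; nothing downstream
# relies on their absolute values except through the normalization rules.

#' Idealized methyl radical
#'
#' Planar D3h CH3: carbon at the origin, hydrogens at 120 degree spacing in
#' the xy-plane. Synthetic spins put +1.05 on carbon and -0.02 on each
#' hydrogen, mimicking Mulliken spin polarization; after heavy-atom
#' normalization the carbon fraction is exactly 1 — the canonical fully
#' localized, sterically bare radical.
#'
#' @param ch_bond C-H bond length, Angstrom, in (0.8, 1.3).
#' @return List with `structure` ([molecular_structure()]) and `spins`.
#' @export
ideal_methyl <- function(ch_bond = 1.08) {
  if (!is.numeric(ch_bond) || length(ch_bond) != 1L || ch_bond <= 0.8 ||
      ch_bond >= 1.3) {
    stop("ch_bond must lie in (0.8, 1.3) Angstrom", call. = FALSE)
  }
  ang <- 2 * pi * (0:2) / 3
  coords <- rbind(c(0, 0, 0),
                  cbind(ch_bond * cos(ang), ch_bond * sin(ang), 0))
  list(structure = molecular_structure(c("C", "H", "H", "H"), coords,
                                       title = "methyl radical",
                                       id = "methyl"),
       spins = c(1.05, -0.02, -0.02, -0.02))
}

# unit vector
unit <- function(v) v / sqrt(sum(v * v))

# three substituent directions around `apex` away from `back`, tetrahedral
# angles, azimuths `phi` (radians) about the apex-back axis
tetrahedral_hydrogens <- function(apex, back, bond = 1.09,
                                  phi = c(pi / 2, pi / 2 + 2 * pi / 3,
                                          pi / 2 + 4 * pi / 3)) {
  v <- unit(apex - back)               # away from the substituent
  ref <- if (abs(v[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  a <- unit(ref - sum(ref * v) * v)    # perpendicular pair a, b
  b <- c(v[2] * a[3] - v[3] * a[2],
         v[3] * a[1] - v[1] * a[3],
         v[1] * a[2] - v[2] * a[1])
  t(vapply(phi, function(p) {
    apex + bond * (v / 3 + (2 * sqrt(2) / 3) * (cos(p) * a + sin(p) * b))
  }, numeric(3)))
}

#' Idealized staggered ethyl radical
#'
#' CH3-CH2 with a planar radical carbon and a staggered methyl group.
#' Synthetic spins localize the unpaired electron on the radical carbon with
#' small hyperconjugative leakage onto the methyl carbon.
#'
#' @return List with `structure` and `spins`.
#' @export
ideal_ethyl <- function() {
  c1 <- c(0, 0, 0)                 # radical CH2 carbon
  c2 <- c(1.49, 0, 0)
  h1 <- rbind(1.08 * c(cos(2 * pi / 3), sin(2 * pi / 3), 0),
              1.08 * c(cos(2 * pi / 3), -sin(2 * pi / 3), 0))
  h2 <- tetrahedral_hydrogens(c2, c1)
  coords <- rbind(c1, c2, h1, h2)
  list(structure = molecular_structure(c("C", "C", rep("H", 5)), coords,
                                       title = "ethyl radical", id = "ethyl"),
       spins = c(1.02, -0.06, -0.02, -0.02, 0.01, 0.01, 0.01))
}

#' Idealized planar allyl radical
#'
#' Three sp2 carbons (C-C 1.40 Angstrom, C-C-C 124 degrees) with in-plane
#' hydrogens. Synthetic spins split the unpaired electron symmetrically over
#' the terminal carbons with negative polarization on the central one — the
#' delocalized, sterically unprotected archetype (maximum fraction below
#' 0.5, low buried volume).
#'
#' @return List with `structure` and `spins`.
#' @export
ideal_allyl <- function() {
  half <- 124 / 2 * pi / 180
  c2 <- c(0, 0, 0)
  c1 <- 1.40 * c(cos(half), sin(half), 0)
  c3 <- 1.40 * c(cos(half), -sin(half), 0)
  h_on <- function(c_this, c_from) {
    # two in-plane H at 120 degrees from the C-C bond
    u <- unit(c_from - c_this)
    rot <- function(th) c(cos(th) * u[1] - sin(th) * u[2],
                          sin(th) * u[1] + cos(th) * u[2], 0)
    rbind(c_this + 1.08 * rot(2 * pi / 3), c_this + 1.08 * rot(-2 * pi / 3))
  }
  h2 <- c2 - 1.08 * c(1, 0, 0)     # central H opposite the bisector
  coords <- rbind(c1, c2, c3, h_on(c1, c2), h2, h_on(c3, c2))
  list(structure = molecular_structure(c("C", "C", "C", rep("H", 5)), coords,
                                       title = "allyl radical", id = "allyl"),
       spins = c(0.58, -0.16, 0.58, -0.01, -0.01, 0.01, -0.01, -0.01))
}

#' Idealized tert-butyl radical
#'
#' A planar central carbon bearing three staggered methyl groups: localized
#' spin with substantial steric shielding of the radical center.
#'
#' @return List with `structure` and `spins`.
#' @export
ideal_tert_butyl <- function() {
  ang <- 2 * pi * (0:2) / 3
  c0 <- c(0, 0, 0)
  cm <- cbind(1.49 * cos(ang), 1.49 * sin(ang), 0)
  hs <- do.call(rbind, lapply(1:3, function(i) {
    tetrahedral_hydrogens(cm[i, ], c0)
  }))
  coords <- rbind(c0, cm, hs)
  list(structure = molecular_structure(c("C", rep("C", 3), rep("H", 9)),
                                       coords, title = "tert-butyl radical",
                                       id = "tert_butyl"),
       spins = c(1.02, rep(-0.05, 3), rep(0.005, 9)))
}

read_packaged_sdf <- function(file) {
  path <- system.file("extdata", file, package = "radstab")
  if (!nzchar(path)) path <- file.path("inst", "extdata", file)
  read_sdf(path)[[1L]]
}

#' TEMPO radical fixture
#'
#' The packaged 2,2,6,6-tetramethylpiperidin-1-oxyl conformer: a static SDF
#' generated once with the MMFF94 force field and frozen (see the file's
#' `_synthetic` label), standing in for a quantum-chemically optimized
#' geometry so that tests never depend on an optimizer. The synthetic spin
#' vector places the unpaired electron on the nitroxide group, split
#' N 0.45 / O 0.55 to mimic its near-degenerate two-center character.
#'
#' @return List with `structure`, `spins`, and the nitroxide atom indices
#'   (`n_index`, `o_index`).
#' @export
tempo_fixture <- function() {
  s <- read_packaged_sdf("tempo_ff_synthetic.sdf")
  s$id <- "tempo"
  n_index <- which(s$elements == "N")
  o_index <- which(s$elements == "O")
  stopifnot(length(n_index) == 1L, length(o_index) == 1L)
  spins <- numeric(n_atoms(s))
  spins[n_index] <- 0.45
  spins[o_index] <- 0.55
  list(structure = s, spins = spins, n_index = n_index, o_index = o_index)
}

#' Trityl radical fixture
#'
#' The packaged triphenylmethyl conformer (MMFF94-generated, frozen SDF,
#' `_synthetic` label). The synthetic spin vector leaves 0.40 on the central
#' carbon and spreads the remainder evenly over the ring carbons with
#' alternating signs — a delocalized yet sterically buried archetype.
#'
#' @return List with `structure` and `spins`.
#' @export
trityl_fixture <- function() {
  s <- read_packaged_sdf("trityl_ff_synthetic.sdf")
  s$id <- "trityl"
  carbons <- which(s$elements == "C")
  central <- carbons[1L]  # first atom of the record is the methyl carbon
  ring <- setdiff(carbons, central)
  spins <- numeric(n_atoms(s))
  spins[central] <- 0.40
  spins[ring] <- 0.60 / length(ring) * rep_len(c(1, -1), length(ring))
  list(structure = s, spins = spins)
}

#' Fixture library spanning the stability map
#'
#' Named list of (structure, spins) fixtures covering all four quadrants of
#' the stability map under the default thresholds: methyl and ethyl
#' (localized, bare), allyl (delocalized, bare), tert-butyl and TEMPO
#' (localized, shielded), trityl (delocalized, shielded).
#'
#' @return Named list of fixtures, each a list with `structure` and `spins`.
#' @export
fixture_library <- function() {
  list(methyl = ideal_methyl(), ethyl = ideal_ethyl(), allyl = ideal_allyl(),
       tert_butyl = ideal_tert_butyl(),
       tempo = tempo_fixture()[c("structure", "spins")],
       trityl = trityl_fixture())
}

#' Synthetic per-atom radical dataset
#'
#' Statistical stand-in for a large deposit of per-atom spin/buried-volume
#' records, for testing the dataset analytics offline. Molecules are drawn
#' from a two-component mixture echoing the empirical shape of large radical
#' datasets: a bulk cluster of localized, sterically bare radicals
#' (maximum fraction 0.45-1, buried volume centered near 25%) and a small
#' designated-stable tail (2% of molecules, at least 3) with low spin
#' (0.18-0.32) and high buried volume (55-70%). Radical-center elements are
#' drawn with carbon-majority proportions (C 0.818, N 0.109, O 0.057,
#' S 0.016). Output is bit-identical for a given `n` and `seed`; the
#' caller's RNG state is left untouched.
#'
#' @param n Number of molecules (>= 10).
#' @param seed Integer seed.
#' @return List with `atoms` (deposit-style per-atom data.frame with columns
#'   `molecule_id`, `atom_index`, `element`, `fractional_spin`,
#'   `percent_buried`), `molecules` (per-molecule summary as from
#'   [load_dataset()]), and `stable_ids` (character).
#' @export
synthetic_dataset <- function(n, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 10) {
    stop("n must be at least 10", call. = FALSE)
  }
  n <- as.integer(n)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  n_stable <- max(3L, round(0.02 * n))
  stable <- c(rep(TRUE, n_stable), rep(FALSE, n - n_stable))
  element <- sample(c("C", "N", "O", "S"), n, replace = TRUE,
                    prob = c(0.818, 0.109, 0.057, 0.016))
  max_frac <- ifelse(stable, stats::runif(n, 0.18, 0.32),
                     0.45 + 0.55 * stats::rbeta(n, 2.5, 1.2))
  vbur <- ifelse(stable, stats::runif(n, 55, 70),
                 pmin(45, pmax(8, stats::rnorm(n, 25, 7))))
  ids <- sprintf("mol%05d", seq_len(n))

  atom_rows <- lapply(seq_len(n), function(i) {
    m <- max_frac[i]
    n_heavy <- max(sample(4:10, 1L), ceiling(1 / m) + 1L)
    n_h <- sample(3:12, 1L)
    # split the residual fraction over the other heavy atoms, keeping the
    # center the strict maximum
    w <- stats::runif(n_heavy - 1L, 0.5, 1.5)
    rest <- (1 - m) * w / sum(w)
    while (any(rest >= m)) rest <- rest * 0.9 + (1 - m) / (n_heavy - 1L) * 0.1
    rest <- rest * (1 - m) / sum(rest)
    heavy_el <- c(element[i],
                  sample(c("C", "N", "O"), n_heavy - 1L, replace = TRUE,
                         prob = c(0.8, 0.12, 0.08)))
    frac <- c(m, rest)
    vb <- c(vbur[i], stats::runif(n_heavy - 1L, 5, max(6, vbur[i])))
    data.frame(
      molecule_id = ids[i],
      atom_index = 0:(n_heavy + n_h - 1L),
      element = c(heavy_el, rep("H", n_h)),
      fractional_spin = c(frac, rep(0, n_h)),
      percent_buried = c(vb, stats::runif(n_h, 2, 20)),
      is_known_stable = stable[i],
      stringsAsFactors = FALSE
    )
  })
  atoms <- do.call(rbind, atom_rows)
  rownames(atoms) <- NULL
  molecules <- stability_record(
    id = ids, max_fraction = max_frac, percent_buried = vbur,
    center_element = element, center_index = 1L
  )
  molecules$is_known_stable <- stable
  list(atoms = atoms, molecules = molecules, stable_ids = ids[stable])
}

#' Serialize a synthetic dataset's per-atom table to CSV lines
#'
#' @param dataset Result of [synthetic_dataset()].
#' @param path Output path, or `NULL` to return lines invisibly.
#' @return Character vector of CSV lines, invisibly.
#' @export
write_dataset_csv <- function(dataset, path = NULL) {
  con <- textConnection("out", "w", local = TRUE)
  utils::write.csv(dataset$atoms, con, row.names = FALSE, quote = FALSE)
  close(con)
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}
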