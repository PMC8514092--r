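---
title: "Scoring organic radical stability: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring organic radical stability: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radstab)
```

## The model

Stable organic radicals are rare because persistence needs two independent
things at once: *thermodynamic* stabilization of the unpaired electron
(delocalization over a π-system or lone pairs) and *kinetic* protection of
the radical center against dimerization and solvent attack (steric
shielding). `radstab` quantifies each with one descriptor computed from a
3D geometry and a per-atom spin-density vector, and combines them into a
single score.

**Maximum fractional spin (thermodynamic).** Raw signed per-atom spin
densities (Mulliken-style populations from any unrestricted quantum-chemistry
calculation) are normalized over the heavy atoms only: hydrogens are removed
from both the sum and the assignment, the absolute magnitudes of the
remaining spins are summed, and each heavy atom receives its fraction of
that sum. Fractions therefore sum to one, a fully localized radical such as
methyl scores exactly 1 on its carbon, and strongly delocalized systems
approach 0.2. The heavy atom with the largest fraction is the *radical
center*; exact ties resolve deterministically to the lowest atom index.
Absolute values are used so that negative spin polarization counts toward
delocalization rather than cancelling; a spin vector that is zero on every
heavy atom has no definable center and is a hard error rather than an
arbitrary assignment.

**Percent buried volume (kinetic).** Around the radical center we place a
sphere of radius $r$ (default 3.5 Å) and measure the percentage of its
volume occupied by the van der Waals spheres of the molecule's atoms,
using unscaled Bondi (1964) radii. The integral is evaluated numerically:
an axis-aligned cubic voxel grid of edge $s$ (default 0.05 Å) is anchored
at the center atom's position; a voxel belongs to the sphere if its center
lies within $r$ of the center atom, and is occupied if its center lies
within the van der Waals radius of any included atom. The percent is
`100 * occupied / total`.

**Radical Stability Score.** The two descriptors combine as

$$\mathrm{RSS} = \%V_\mathrm{bur} + w\,(1 - \text{max fractional spin}),
\qquad w = 50 .$$

The buried-volume term enters on the 0–100 percent scale; with $w = 50$
the spin term spans 0–50, comparable to the observed buried-volume range
(≈13 for methyl up to ≈65–70 for nitroxides like TEMPO), which is the
"approximately equal weight" rationale for the default. RSS is ordinal: it
ranks candidates, it does not predict half-lives or rate constants.

## Parameters that matter

| parameter | default | units | notes |
|---|---|---|---|
| `sphere_radius` | 3.5 | Å | descriptor values at 2.5–4.0 Å are very highly correlated (`radius_robustness()`), so the familiar 3.5 Å is kept |
| `spacing` | 0.05 | Å | voxel edge; must be ≤ `sphere_radius/10` |
| `radii` | `"bondi"` | Å | unscaled Bondi set; unknown elements are a hard error |
| `include_center_atom` | `TRUE` | — | see below |
| `include_hydrogens` | `TRUE` | — | sensitivity toggle only |
| `weight` | 50 | — | RSS spin-term multiplier |

**Why the center atom occupies voxels.** The organometallic buried-volume
tradition excludes the central (metal) atom because the ligand, not the
metal, is the object of study. Here the sphere is centered on an atom *of
the molecule itself*, and the descriptor's reference anchor values (methyl
≥ 13%) are only reachable when the center atom's own sphere counts: with
the center excluded, methyl drops to roughly 4%. Both conventions are
exposed; including the center is the default and the one used everywhere in
the package. This is a convention choice on a point the descriptor's
literature leaves open, not a derived fact.

## Numerical choices

* **Voxel membership** uses voxel centers, no partial-volume weighting. At
  0.05 Å spacing the residual error against the closed-form single-sphere
  value is below 0.02 percentage points, and the error decreases strictly
  with refinement (checked at 0.2/0.1/0.05 Å).
* **Grid anchoring.** The grid is anchored at the center atom, so the
  result is exactly translation-invariant. Rotations can shift voxel
  centers relative to atom spheres; this grid-alignment jitter is bounded —
  measured below 0.01 points for methyl, asserted below 0.15 in the tests.
* **Reach pre-filter.** Atoms with `distance(center) − vdW > sphere_radius`
  cannot touch the sphere and are skipped; the result is bit-identical.
* **A small-molecule subtlety.** For a molecule whose entire van der Waals
  union fits inside every atom's sampling sphere (methyl is one), the
  per-atom buried volumes are all equal up to grid jitter — the occupied
  *set* is the same, only the grid alignment differs. Strict
  center-vs-periphery orderings only appear once the molecule outgrows the
  sphere (tert-butyl already shows it).
* **Pareto dominance** (maximize %V~bur~, minimize max spin) uses weak
  inequalities plus at least one strict; records duplicated exactly in both
  coordinates dominate neither each other nor themselves and are all
  retained. The sorted-sweep implementation is tested for exact equality
  against an O(n²) brute-force oracle, ties included.
* **Percentile convention.** `percentile_rank(values, x)` is
  `100 · #{values ≤ x}/N` (weak inequality): a stable radical tied with the
  dataset maximum ranks 100, and "in or above the *p*-th percentile" reads
  naturally as `min stable percentile ≥ p`. No interpolation.
* **R²** is the squared Pearson correlation throughout; degenerate
  (zero-variance) inputs error rather than returning `NA`.

## Fixtures and the synthetic dataset

The package is fully testable offline. Idealized geometries (planar methyl,
staggered ethyl, planar allyl, tert-butyl) are built from closed-form
internal coordinates; TEMPO and trityl conformers were generated once with
the MMFF94 force field and frozen as plain-text SDF fixtures (filenames
carry a `_synthetic` label: they stand in for quantum-chemically optimized
geometries, and their buried volumes inherit force-field accuracy — a few
percentage points). Their spin vectors are hand-designed to be plausible
(spin polarization signs, N/O near-degeneracy of 0.45/0.55 for the
nitroxide, 0.40 on trityl's central carbon), not DFT-accurate; no test
relies on their absolute values except through the normalization rules.
Under the default map thresholds (spin 0.5, buried volume 40 — heuristic
cutoffs, exposed as arguments) the six fixtures cover all four quadrants of
the stability map.

`synthetic_dataset(n, seed)` emulates the *statistical shape* of a large
radical dataset: a bulk cluster of localized, sterically bare radicals
(max fraction 0.45–1 with density piling toward 1, buried volume ≈ N(25, 7)
clamped to [8, 45]) and a small designated-stable tail (2% of molecules,
at least 3; max fraction U(0.18, 0.32), buried volume U(55, 70)), with
radical-center elements drawn at the carbon-majority proportions
C 0.818 / N 0.109 / O 0.057 / S 0.016. Per-molecule values are expanded
into deposit-style per-atom tables (center fraction kept the strict
maximum, hydrogens at exactly zero) so the dataset loader's recomputation
and cross-checking paths are exercised. It does **not** emulate real
chemistry: no correlation between spin and sterics within the bulk, no
conformer noise, no BDE/RSE columns. Tests passing on it demonstrate the
*analytics* (grouping, enrichment, counting) are correct, not that any
chemical conclusion transfers.

## Problem sizes

The test suite and acceptance script run at desk scale: full-resolution
(0.05 Å) grids for the single-atom, methyl and TEMPO anchors, 0.1 Å grids
for multi-structure sweeps (radius robustness over four fixtures, per-atom
sweeps of 13-atom tert-butyl), Pareto oracle comparisons up to n = 2000,
and synthetic datasets up to n = 2000. The grid engine is vectorized,
about 1.4 million voxels per call at default settings.

## Known limitations

* Spin provenance is not validated: any per-atom signed vector is accepted,
  whether Mulliken, Löwdin or invented. Consistency with a given level of
  theory is the caller's responsibility.
* Charge is carried as metadata only; charged radicals are scored
  identically to neutral ones.
* Connectivity from SDF bond blocks is not retained in the structure
  container — nothing downstream needs bonds, since the descriptor is
  purely distance-based.
* The quadrant labels are descriptive conveniences; the literature provides
  no universal cutoffs, and none are claimed.
* RSS is a screening metric. High-scoring candidates still need synthesis
  and kinetics to be called stable.
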