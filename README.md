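# radstab

Quantitative scoring of organic free-radical stability from two
complementary molecular descriptors:

* **maximum heavy-atom fractional spin** — how localized the unpaired
  electron is (thermodynamic stabilization via delocalization). Raw signed
  per-atom spin densities are normalized over heavy atoms only
  (`fraction_i = |s_i| / Σ_heavy |s_j|`, hydrogens excluded), and the atom
  with the largest fraction is the radical center;
* **percent buried volume (%V_bur)** — how sterically shielded the radical
  center is (kinetic persistence). A sphere of radius 3.5 Å centered on
  the radical center is voxelized on a 0.05 Å Cartesian grid, and the
  occupied percentage is the fraction of voxel centers falling inside the
  unscaled Bondi van der Waals sphere of any atom.

The two combine into the **Radical Stability Score**

```
RSS = %V_bur + 50 × (1 − max fractional spin)
```

so that experimentally stable radicals (TEMPO, proxyl, trityl — delocalized
*and* shielded) score high while small transient radicals like methyl score
low. The package also extracts element-stratified **Pareto fronts** (maximize
%V_bur, minimize max spin) to shortlist candidate stable radicals, and
reproduces dataset-level analytics (center-element counts, percentile
enrichment of known stable species, descriptor correlations, sphere-radius
robustness) over deposit-style per-atom CSV tables.

It is aimed at computational and physical-organic chemists screening
radicals for applications — redox-flow batteries, organic electronics, spin
labels — where long-lived open-shell species are the design goal.

## Worked example

```r
library(radstab)

m <- ideal_methyl()                       # planar CH3, C–H 1.08 Å,
                                          # spins C +1.05, H −0.02 each
fs <- fractional_spins(m$structure, m$spins)
fs
#> fractional_spins: center C(atom 1), max fraction 1

bv <- buried_volume(m$structure, radical_center(fs))
bv
#> buried volume: 14.59% (209539 / 1436297 voxels), center atom 1

radical_stability_score(bv$percent_buried, fs$max_fraction)
#> [1] 14.58884
```

The spin on methyl's carbon normalizes to exactly 1 (hydrogens are excluded
from the scheme), and its buried volume of ≈14.6% is at the bare end of the
descriptor's range — the archetypal unstable radical, with an RSS equal to
its buried volume because the spin term vanishes at full localization. For
contrast, the packaged TEMPO conformer:

```r
t <- tempo_fixture()
rec <- score_structure(t$structure, t$spins)
rec[, c("id", "max_fraction", "percent_buried", "rss", "center_element")]
#>      id max_fraction percent_buried      rss center_element
#> 1 tempo         0.55       46.90555 69.40555              O
max(buried_volume(t$structure, t$n_index)$percent_buried,
    buried_volume(t$structure, t$o_index)$percent_buried)
#> [1] 68.17142
```

Delocalization over the nitroxide N–O pair plus the shielding of four
flanking methyls put TEMPO far up the score scale. Pareto selection over a
record table:

```r
recs <- stability_record(c("A", "B", "C"), c(0.2, 0.5, 0.6), c(60, 65, 30),
                         c("C", "C", "C"))
pareto_front(recs)$frontier$id
#> [1] "A" "B"     # C is dominated by B on both axes
```

A command-line interface wrapping the same functions ships at
`inst/cli/radstab` (`score`, `burvol`, `pareto`, `map`, `dataset`,
`fixtures` subcommands).

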