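Package: radstab
Title: Radical Stability Scoring from Spin Densities and Buried Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the stability of organic free radicals from two
    complementary molecular descriptors: the maximum heavy-atom fractional
    spin density (a thermodynamic measure of electron delocalization) and
    the percent buried volume around the radical center (a kinetic measure
    of steric protection), computed by voxel integration on a Cartesian
    grid with unscaled Bondi van der Waals radii. The two descriptors are
    combined into a single Radical Stability Score and used for
    element-stratified Pareto-front selection of candidate stable radicals.
    Includes readers and writers for XYZ and SDF V2000 geometries, parsers
    for per-atom Mulliken spin-density tables and quantum-chemistry log
    output, idealized geometry fixtures, a synthetic dataset generator, and
    a command-line interface for batch scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
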