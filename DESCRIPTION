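Package: cageforge
Title: Fragment-Based Design of Two-Component Tetrahedral Protein Cages
Version: 0.1.0
Authors@R:
    person("cageforge", "developers", email = "cageforge@example.org",
           role = c("aut", "cre"))
Description: Tools for fragment-based rigid-body docking and interface
    analysis of two-component symmetric protein assemblies, centred on the
    tetrahedral T:{C3}{C3} architecture built from two C3 trimers. Provides
    a lightweight PDB structure model with point-group expansion, a
    fragment-pair cluster database with per-position amino-acid frequencies
    and interaction weights, ghost-fragment observation matching and the
    normalized Nanohedra score, grid docking with transform-hash clustering
    and local grid optimization, position-specific amino-acid profiles
    (fragment, evolutionary, tertiary blend) with cross-entropy and
    profile-loss triage, a suite of interface metrics (Shrake-Rupley SASA,
    buried surface area, core/rim/support classes, composition similarity,
    secondary-structure fractions, hydrogen bonds, hydrophobic collapse
    sites, spike ratio), weighted pose/design selection, and deterministic
    synthetic-structure generators used as the package's test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
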