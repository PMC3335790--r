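Package: tmbundle
Title: Comparative Analysis of GPCR Seven-Transmembrane Helix Bundles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extraction, superposition and comparison of the 200-residue
    heptahelical transmembrane (7TM) bundle shared by class A G
    protein-coupled receptors. Defines the bundle in Ballesteros-Weinstein
    coordinates from per-receptor anchor maps, superposes bundles by a
    secondary-structure-matching rigid fit onto a common reference,
    computes pairwise RMSD and sequence-identity grids averaged by
    receptor pair, per-position C-alpha deviation profiles, five-section
    membrane-slab RMSDs, isolated-helix rigid-body comparisons, ionic-lock
    salt-bridge censuses, and hydrogen-bond-based helix assignment with
    kink measures. Includes a synthetic 7TM bundle generator with
    controllable rigid-body helix perturbations so every stage is testable
    without structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
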