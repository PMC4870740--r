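Package: xbsf
Title: Empirical Halogen-Bond Scoring and Rescoring of Protein-Ligand Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects C-X...A halogen-bond interactions (X = Cl, Br, I;
    A = O, N, S) in protein-ligand structures and scores them with an
    empirical energy E = W * Phi * D built from a sigma-hole angle factor,
    a polar-flattening-corrected van der Waals overlap distance factor,
    and per-halogen weights. Reads PDB and multi-MODEL PDBQT pose files,
    mines contact geometries into angle/distance histograms, builds
    docking grid boxes with padded extents and seeded randomized shifts,
    computes in-place heavy-atom pose RMSD, and generates synthetic
    protein-ligand fixtures with exactly specified halogen-bond geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
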