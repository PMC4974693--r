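Package: xtalvar
Title: Ensemble Comparison of Protein-Inhibitor Cocrystal Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing ensembles of protein-inhibitor cocrystal
    structures sharing one protein, in the style of comprehensive
    dipeptidyl peptidase IV (DPP-4) cocrystal surveys. Extracts analysis
    units (one protein chain, its bound inhibitor and nearby crystal
    waters) from PDB files, performs all-pairs Kabsch superposition with
    RMSD summaries, computes per-residue C-alpha and side-chain variation
    profiles, derives a contact-frequency inhibitor binding area and
    distance-based binding-mode classifications, detects conserved
    crystallographic water sites with B-factor annotation, and profiles
    per-residue solvent-accessible surface area (Shrake-Rupley). Includes
    a synthetic-ensemble generator with known ground truth so every stage
    is testable without downloading structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
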