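Package: hydroscan
Title: Solvent Accessibility and Conservation-Based Prediction of Surface
    Hydrophobic Residues
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies and predicts solvent-exposed versus buried
    hydrophobic residues in proteins. Computes per-atom accessible surface
    area from PDB structures with the Lee-Richards slice method, aggregates
    it to per-residue relative solvent accessibility (RSA) against extended
    Ala-X-Ala reference areas and classifies residues at a 7 percent RSA
    threshold. From labelled residue sets it derives surface, buried and
    flanking-position propensities. From query-anchored multiple alignments
    it computes a per-residue hydrophobicity conservation score, bins it,
    and converts bin frequencies into confidence scores used to predict the
    solvation state of hydrophobic residues from sequence alone, with an
    optional flanking-window refinement. Ships a synthetic fixture
    generator for structures and alignments with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
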