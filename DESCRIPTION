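Package: PepDock
Title: Ensemble Rigid-Body Protein-Peptide Docking with Conformational Selection
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for information-driven protein-peptide docking by
    conformational selection. Builds canonical peptide conformers (extended,
    alpha-helix, polyproline II) from sequence by internal-coordinate chain
    extension, derives ambiguous interaction restraints from a broad binding-site
    definition, performs ensemble rigid-body docking with a weighted composite
    score (restraint, van der Waals, electrostatic and desolvation energies plus
    buried surface area), quantifies conformational selection via enrichment
    factors, assesses models with peptide-adapted CAPRI metrics (i-RMSD, l-RMSD,
    l-i-RMSD, Fnat) and ranks solutions by RMSD-based clustering. Includes a
    deterministic generator of toy receptor-peptide complexes for testing and
    benchmarking without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
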