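Package: lariatforge
Title: Design and Validation Toolkit for Macrocyclic Peptide-Small Molecule Conjugates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for designing lariat-shaped thioether-macrocyclized
    peptide-small molecule conjugates against a receptor pocket. Covers closed
    macrocycle backbone sampling with cyclic-coordinate-descent ring closure,
    torsion-bin and hydrogen-bond-pattern clustering, dipeptide anchor extension,
    rigid-body grafting by Kabsch superposition, a declared simplified design
    score function with simulated-annealing sequence design, protein-ligand
    interface metrics (binding energy difference, shape complementarity, buried
    surface area, contact molecular surface, buried unsatisfied polars, pocket
    volume), percentile/loop-contact/diversity design filtering, ensemble
    validation statistics (contact fractions, hydrogen bonds, C-alpha distance
    tables, k-means RMSD clustering), and quantitative pharmacology (constrained
    logistic fits, Cheng-Prusoff, Schild regression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
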