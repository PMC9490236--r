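Package: cycpep
Title: Design and Analysis of Membrane-Permeable Peptide Macrocycles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for desk-scale computational design of head-to-tail cyclized
    peptide macrocycles (6-12 residues) with mixed L/D chirality and backbone
    N-methylation. Implements analytic kinematic closure of cyclic backbones,
    a surrogate scoring function with backbone hydrogen-bond detection
    and unsatisfied-donor analysis, an iterative sequence-design protocol that
    removes exposed amide NH groups by proline substitution or N-methylation,
    energy-landscape structure prediction with symmetry-aware backbone RMSD and
    energy-based clustering, torsion-bin-string clustering under cyclic and
    mirror symmetry, genetic-algorithm multistate design of conformation-
    switching (chameleonic) macrocycles, and apparent-permeability (PAMPA)
    calculations from donor/acceptor concentration measurements.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
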