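Package: qsar3d
Title: Lattice-Field 3D-QSAR and Pharmacophore Screening for Sulfonamide
    Carbonic Anhydrase Inhibitors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ligand-based 3D-QSAR modelling in the CoMFA/CoMSIA tradition:
    steric (Lennard-Jones) and electrostatic (Coulomb) probe fields and
    Gaussian similarity indices sampled on a regular lattice around aligned
    small molecules, regressed against inhibitory potency by partial least
    squares with leave-one-out cross-validation, region focusing and
    favoured/disfavoured contour extraction.  Ships a 41-compound
    diarylpyrazole-benzenesulfonamide human carbonic anhydrase II benchmark
    with its published train/test/validation splits, a seeded synthetic
    generator that plants known field-activity structure for property-based
    testing, and a virtual-screening funnel (common-feature pharmacophore,
    Lipinski rule of five, descriptor-range and chemical-space filters).
    Conformer embedding and atomic charges are delegated to RDKit through a
    bundled helper script.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
SystemRequirements: Python (>= 3.8) with the rdkit package on PATH as
    'python' (used for 3D conformer embedding and Gasteiger charges)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
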