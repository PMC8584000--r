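Package: dockgen
Title: Docking-Score-Guided De Novo Molecule Generation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: De novo design of drug-like small molecules by global
    optimization over SMILES strings. A multilayer-perceptron surrogate
    predicts protein-ligand docking energies from a 2232-dimensional
    feature vector (2048-bit path fingerprint, 167 MACCS-key slots and 17
    molecular descriptors), and a conformational-space-annealing (CSA)
    optimizer searches chemical space for molecules that minimize a
    weighted objective combining predicted docking energy, drug-likeness
    (QED) and Tanimoto similarity to a reference molecule, with
    Lipinski-rule penalties. Includes a deterministic pseudo-docking
    oracle and fragment-based SMILES generator for fully reproducible
    desk-scale experiments, and an optional adapter for an external
    docking engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
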