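Package: polytag
Title: Head and Tail Atom Assignment for Polymer Repeat Units
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies the polymerizing monomer in a reaction SMILES,
    assigns a polymer class (polyvinyl, polyamide, polyester, polyether,
    polyurethane) and polymerization mechanism from functional-group
    SMARTS patterns, ranks candidate reactive sites with a
    quantum-chemical nucleophilicity index computed from the Mulliken
    population of the HOMO at the RHF/STO-3G level (an in-process SCF
    engine with McMurchie-Davidson integrals is included), performs
    graph-based ring-opening and condensation edits, and emits valid
    repeat-unit SMILES with head ([*:1]) and tail ([*:2]) atoms tagged.
    Includes a validation harness that scores predictions against
    ground-truth tagged SMILES under head/tail token equivalence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with the RDKit package available as
    'python' on the PATH (or via options(polytag.python=)).
Config/testthat/edition: 3
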