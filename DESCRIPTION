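Package: anisofit
Title: Equilibrium Speciation, Anisotropy Titration Fitting, and
    Allosteric Coupling for Tetrameric DNA-Binding Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the equilibrium thermodynamics of DUF156-family
    transcriptional repressors (FrmR, RcnR) and similar tetrameric
    DNA-binding sensors. Represents small binding schemes as components
    plus complexes and solves the coupled mass-balance equations;
    simulates and fits fluorescence-anisotropy titrations under the
    two-nondissociable-tetramer equal-affinity model, with stoichiometric
    breakpoint analysis and detection-limit (lower-bound) reporting;
    computes allosteric coupling free energies from pairwise permutations
    of apo and effector-bound DNA affinities; and implements an
    intracellular fractional-occupancy model of formaldehyde partitioning
    between a trace sensor and the bulk glutathione pool. Includes a
    seeded synthetic-titration generator and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
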