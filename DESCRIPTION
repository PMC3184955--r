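Package: amelnmr
Title: NMR-Derived Structural Inference for Amelogenin
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for chemical-shift-based structural analysis of the
    enamel matrix protein amelogenin: secondary chemical shifts versus
    random-coil references with pre-proline handling, scalar-coupling and
    heteronuclear-NOE classification, NOE connectivity tabulation,
    consensus helix/PPII/coil segment calling with fragment-overlap
    stitching, geometric polyproline-II detection from backbone
    coordinates, chemical-shift-perturbation mapping of assembly
    interfaces, analytical-ultracentrifugation stoichiometry, and a
    coarse-grained hollow-shell nanosphere builder. Includes seeded
    synthetic-data generators with planted ground truth for every input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
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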