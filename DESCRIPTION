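Package: ephscore
Title: Nonempirical Long-Range Interaction-Energy Scoring of EphA2-Ephrin A1 Inhibitors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for ranking inhibitors of the EphA2-ephrin A1
    protein-protein interaction with nonempirical interaction-energy models.
    Implements the hybrid variation-perturbation theory (HVPT) ledger that
    composes multipole-electrostatic, penetration, exchange, delocalization
    and correlation components into consecutive theory levels; a long-range
    physics core (cumulative atomic multipole electrostatics truncated at the
    inverse fourth power of distance, and Tang-Toennies damped atom-atom
    dispersion); ranking statistics (Pearson correlation with orientation
    handling, the Npred concordant-pair success rate with experimental-tie
    exclusion, and the standard error of estimate); a solvation-free-energy
    applicability screen with reduced-set re-evaluation; and a seeded
    synthetic-series generator for congeneric ligand sets.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
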