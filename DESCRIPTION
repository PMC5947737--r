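Package: c4ebm
Title: Cell-Type-Specific Electron Transport and Energy Budgets of C4 Photosynthesis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analytical model of light absorption, linear versus cyclic electron
    transport partitioning, and ATP/NADPH energy budgets in the bundle-sheath and
    mesophyll cells of C4 leaves. Computes per-cell-type light absorption from
    interveinal leaf geometry via a serial Beer-Lambert cascade, the whole-leaf
    electron budget and quantum yield of CO2 assimilation under NADPH and ATP
    co-limitation, the cell-type partitioning of electron fluxes given photosystem
    distributions, per-CO2 energy demand stoichiometries for the NADP-ME, NAD-ME
    and PEP-CK decarboxylation subtypes and their mixtures, and the demand-supply
    matching problems that diagnose which decarboxylation mixtures are
    physiologically feasible.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
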