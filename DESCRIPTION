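Package: leafcbm
Title: Constraint-Based Modeling of C3 Leaf Carbon Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compartmentalized constraint-based modeling of central carbon
    metabolism in C3 photosynthetic leaves. Provides flux balance analysis
    with a biomass objective, RuBisCO carboxylation/oxygenation (Vc/Vo)
    ratio coupling, total-flux-minimizing canonical solutions, flux
    variability and gap detection, flux-sum metabolite turnover analysis,
    CO2 source attribution and compartmental energy/redox budgets, and
    declarative stress-scenario simulation (photorespiration sweeps,
    stomatal CO2 restriction, PEP carboxylase elevation) together with
    flux-versus-expression concordance checks. Ships a curated synthetic
    four-compartment leaf model plus SBML Level 3 FBC and TSV model I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
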