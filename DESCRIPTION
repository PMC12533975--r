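Package: fluxkit
Title: Constraint-Based Metabolic Modelling with Enzyme and Thermodynamic
    Constraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for constraint-based analysis of medium-scale
    metabolic network models. Provides stoichiometric model input/output
    (COBRA-style JSON and SBML Level 3 with FBC), flux balance analysis and
    parsimonious FBA on a built-in bounded-variable simplex solver,
    production envelopes, a typed reaction-enzyme-polypeptide-gene
    knowledge graph with gene-protein-reaction rule derivation and
    knockout-disruption classification, enzyme-constrained (sMOMENT-style)
    model construction with turnover-number fitting across growth
    conditions, elementary flux mode enumeration with growth/yield Pareto
    analysis, saturation FBA over external substrate concentrations, and
    probabilistic max-min driving force analysis under correlated
    uncertainty in standard reaction Gibbs energies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    igraph,
    quadprog,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
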