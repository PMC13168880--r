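Package: cosleaf
Title: Coupled COS-CO2-H2O Leaf Cuvette Gas-Exchange Model and Inversion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Steady-state leaf/cuvette gas-exchange model coupling carbonyl
    sulfide (COS), CO2 and water vapour through a shared stomatal pathway,
    with ternary water-vapour corrections, carbonic-anhydrase mesophyll
    conductance, Farquhar-type RuBisCO kinetics and a temperature-dependent
    COS compensation point. Includes weighted least-squares inversion of the
    physiological state vector against cuvette observations, Monte Carlo
    posterior ensembles with correlated-draw forward spread, compensation
    point estimation by regression and by algebraic layer inversion, and a
    synthetic cuvette-experiment generator for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
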