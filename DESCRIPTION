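Package: carboniso
Title: Chamber CO2 Flux Inversion, Xylogenesis Phenology and Carbon-13
    Allocation Coherence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of tree carbon allocation from automated
    chamber measurements of 12CO2 and 13CO2. Inverts closed-chamber
    concentration traces to per-isotopologue fluxes and the delta13C of
    shoot assimilation and stem and soil CO2 effluxes, fits Gompertz curves
    to tracheid phenophase counts to derive wood growth rates and growth
    periods, detrends fluxes and root growth against temperature and soil
    moisture before fitting linear and mixed-effects association models
    with non-structural carbohydrate pools, and quantifies lead/lag
    structure between delta13C of assimilation and of respiratory effluxes
    by Morlet wavelet coherence with AR(1)-surrogate significance testing.
    Includes a synthetic-data generator with known ground truth so the full
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    nlme,
    stats,
    utils,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    deSolve,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
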