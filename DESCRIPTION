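Package: agrorisk
Title: Soil Antibiotic Pollution Risk, Spatial Upscaling, and Risk-Yield
    Tradeoff Thresholds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for ecotoxicological risk assessment of antibiotic
    mixtures in agricultural soil and for linking those risks to land
    system intensification. Implements predicted no-effect concentration
    (PNEC) derivation with assessment factors and equilibrium
    soil-water partitioning, per-compound and concentration-addition
    cumulative risk quotients, ensemble random-forest spatial upscaling
    with Monte-Carlo uncertainty maps, watershed-level aggregation with
    AICc multimodel-averaged regressions across nested spatial scales,
    constraint-line (quantile boundary) analysis, and inverted-U
    (development Kuznets curve) threshold estimation for risk-yield
    tradeoffs. Ships a seeded synthetic-landscape generator with planted
    ground truth so the full pipeline is testable end to end without
    external geodata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    mgcv,
    ranger,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
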