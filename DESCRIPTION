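Package: thermofruit
Title: Temperature and Stress-Duration Effects on Tomato Pollen, Seed Set,
    and Fruit Mass
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Process-based model of tomato reproduction under temperature
    stress. Pollen number per flower follows a constrained beta function of
    temperature; pollen viability and germination follow quadratic
    temperature-by-duration response surfaces; seed number and individual
    fruit mass follow linear links, giving a five-stage cascade from a
    temperature regime to fruit mass. The package provides the deterministic
    cascade, per-stage least-squares parameter estimation with RMSE and
    R-squared reporting, a synthetic factorial-experiment generator with
    Poisson/binomial/Gaussian observation noise for parameter-recovery
    studies, and reporting utilities (response-surface grids, truss-level
    yield decomposition).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
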