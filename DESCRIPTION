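Package: hsmrf
Title: Hierarchical Structural Models of V1 Population Receptive Fields
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates receptive fields of local populations of primary
    visual cortex neurons that share a small pool of thalamic-like inputs.
    Implements a three-layer feedforward encoding model (difference-of-
    Gaussians LGN units, softplus hidden and output layers) fitted jointly
    to the whole population by Poisson maximum likelihood with analytic
    gradients, bound constraints and random-restart model selection; a
    Laplacian-regularized linear-nonlinear baseline with a histogram point
    nonlinearity; evaluation statistics (prediction correlation,
    signal/noise power decomposition, fraction of explained variance with
    a high-noise exclusion rule, model linearization and a non-linearity
    index); and a synthetic-population generator producing datasets with
    the exact single-trial/multi-trial layout of the recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
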