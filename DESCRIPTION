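Package: adlmsm
Title: Continuous-Time Multi-State Markov Models for ADL Disability Transitions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Panel-data maximum likelihood estimation of a three-state
    continuous-time Markov model for transitions between no, mild and severe
    disability in activities of daily living (ADL) among older adults.
    Provides ADL score classification, long-format panel data ingestion and
    validation, transition-frequency tables, transition intensity matrices
    with covariate effects proportional on the intensity scale, one-year
    transition probabilities via the matrix exponential, Wald hazard-ratio
    tables, prevalence-based goodness of fit, and a synthetic cohort
    generator with known ground truth for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
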