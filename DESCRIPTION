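Package: respox
Title: Respiratory System Modelling and Adaptive Oxygen-Supply Control
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Lumped-parameter modelling of the human respiratory system and
    closed-loop simulation of automatic oxygen titration for respiratory
    distress patients. Builds per-generation airway resistance, inertance and
    compliance from Weibel-type morphometry, assembles second-order airway
    transfer functions and a three-compartment alveolar gas-exchange model
    with transport delays, and simulates set-point tracking of SpO2 under a
    conventional PID controller, an MIT-rule model-reference adaptive
    controller (MRAC), and a set-point-modulated fuzzy-PI adaptive controller
    (SFPIMRAC) whose adaptation gain is produced online by Mamdani fuzzy
    inference from the model-following error and its rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
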