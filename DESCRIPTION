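Package: bcisim
Title: Closed-Loop Simulation of Intracortical Brain-Computer Interfaces
    with Emulated Motor-Cortex Firing Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A human-in-the-loop model system for intracortical
    brain-computer interface (iBCI) research. Maps finger-joint kinematics
    (19-sensor data-glove trials) to emulated primary-motor-cortex firing
    rates through a time-delay neural network with session-specific readout
    modules, decodes the emulated rates into 2D cursor velocity with a
    steady-state velocity Kalman filter, and runs a closed-loop center-out
    cursor task at a 25 ms tick. Includes a synthetic-data generator with
    ring-structured population geometry and rotational latent dynamics,
    Hungarian trial pairing across modalities, a neural-statistics
    validation battery (peri-event averages, PCA cluster geometry with a
    permutation Mantel test, jPCA rotational modes, ellipse-based
    generalization statistics), and the seven standard center-out
    behavioral measures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    clue,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
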