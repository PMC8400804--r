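Package: ffcsim
Title: Cycle-Level Simulation of a Digital Fuzzy Feedback Controller for
    Closed-Loop Functional Electrical Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Desk-scale software model of an integer-arithmetic digital
    fuzzy feedback controller (FFC) for closed-loop functional electrical
    stimulation of knee extension.  Provides a bit-exact Takagi-Sugeno
    fuzzy logic controller datapath (8-bit input scaling, triangular
    membership functions, a 25-rule min-inference base and singleton
    centre-of-gravity defuzzification), a matching floating-point
    reference pipeline, cycle-level finite-state-machine simulation of the
    ADC data-acquisition handshake, error-conversion datapath and stimulus
    pulse-width generator at a 1 MHz tick, a configurable knee-extension
    plant (first-order muscle activation feeding nonlinear second-order
    shank dynamics), closed-loop simulation at 100 ms sampling, and
    step-response metrics (rise time, 2 percent settling time, overshoot,
    steady-state error).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
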