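Package: pendelay
Title: Delayed-Feedback Inverted-Pendulum Models of Standing Balance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing standing balance as a linearized single
    inverted pendulum stabilised by delayed proportional-derivative feedback.
    Computes stability regions in the dimensionless gain plane, generalized
    critical-damping (unique multiple root) feedback gains for PD, damped-PD,
    PDA and PID controller variants via Pade-approximated characteristic
    polynomials, simulates the closed loop as a delay differential equation
    with a torque decomposition into centre-of-mass and centre-of-pressure
    components, solves the co-adaptation problems linking ankle stiffness,
    neural delay and sensorimotor gains, and decomposes multi-joint linear
    delayed-feedback systems into independent single-joint modes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
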