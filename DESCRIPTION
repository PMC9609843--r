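Package: glycosim
Title: Closed-Loop Glucose-Insulin Control Simulation Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for closed-loop glycemic control in type-1
    diabetes built around an identified third-order glucose-insulin deviation
    model. Provides the discrete and continuous plant descriptions with
    structural (controllability/observability) analysis, synthesis of three
    control laws (discrete PID, linear quadratic regulation via algebraic
    Riccati solvers, and first-order sliding-mode control with Lyapunov
    reaching diagnostics), a fixed-step closed-loop simulation engine with
    matched sinusoidal disturbances, time-response performance metrics
    (settling time, rise time, overshoot, steady-state error, chattering),
    and command-line entry points for reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
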