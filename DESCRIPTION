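Package: mitodyn
Title: Relaxation-Oscillator Modelling of Mitochondrial Fission-Fusion
    Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates mitochondrial fission-fusion dynamics as a
    three-variable relaxation oscillator of Oregonator
    (Belousov-Zhabotinsky) type, in which the fission factor (DRP1) acts
    as autocatalytic activator, the MiD49/51 adaptors as intermediary and
    the fusion factors (MFN1/2, OPA1) as delayed negative feedback.
    Provides stiff integration of the model under named parameter regimes
    (normal, diseased, therapy), fixed-point and linear stability
    analysis, oscillation metrics (period, frequency, amplitude, mean
    level, fission-fusion phase lag), phase-plane orbits and nullclines,
    parameter sensitivity sweeps with Hopf-boundary location, condition
    contrasts with machine-checkable verdicts, and a seeded generator of
    replicate-level noisy observations for two-condition comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    withr,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
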