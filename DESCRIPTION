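Package: vigilcpt
Title: Simulation and Spectral Analysis of Sustained-Attention Reaction Times
Version: 0.1.0
Authors@R: person("Vigil", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying moment-to-moment fluctuations of sustained
    attention in continuous performance task (CPT) data. Simulates
    Vigil-CPT-structured trial logs with group-level reaction-time structure
    (baseline, linear time-on-task trend, infraslow sinusoidal oscillation,
    lapse and commission processes), classifies responses under an extended
    response window, quantifies the vigilance decrement through block-wise
    coefficients of variation and a mixed-effects model with Satterthwaite
    degrees of freedom and Tukey-adjusted contrasts, computes Lomb-Scargle
    periodograms of the unevenly sampled correct-response RT series, and
    locates group differences in infraslow spectral power with cubic-spline
    smoothing and pointwise functional F- and t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    Matrix,
    numDeriv,
    jsonlite,
    MASS,
    splines,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
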