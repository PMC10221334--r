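Package: slopeBE
Title: Average-Slope Absorption-Rate Metrics in Simulated Bioequivalence Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Joint pharmacokinetic-bioequivalence simulation toolkit for
    studying absorption-rate metrics. Simulates 2x2 crossover bioequivalence
    trials from one- and two-compartment oral absorption models with lognormal
    between- and within-subject variability, estimates non-compartmental
    metrics (Cmax, Tmax, AUC, AUCinf) together with the average slope (AS) and
    weighted average slope (ASw) of the rising limb of the concentration-time
    curve, quantifies each metric's kinetic sensitivity to absorption-rate
    differences through Monte Carlo sweeps over the test/reference Ka ratio,
    and examines the correlation structure of the metrics by principal
    component analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
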