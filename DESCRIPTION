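Package: prostasim
Title: Mechanistic Simulation of 5-Alpha-Reductase Inhibition and Prostate Maintenance in the Rat
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiscale dynamic model of androgen-regulated ventral prostate
    maintenance in the adult male rat under 5-alpha-reductase inhibition by
    finasteride. Couples a two-compartment oral drug pharmacokinetic model,
    hepatic 5aR1 metabolism under competitive inhibition, mass-action
    prostatic 5aR2 kinetics with two-step time-dependent inhibition,
    androgen-receptor binding with quasi-equilibrium dimerization and gene
    occupancy, occupancy-driven prostate mass dynamics, and the
    testicular-pituitary feedback axis. Provides steady-state-forced
    initialization, stiff simulation of intact, castration and dosing
    scenarios, calibration to sampled study data, control-coefficient
    sensitivity analysis, and dose-by-interval response surfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
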