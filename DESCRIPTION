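Package: dlgnIN
Title: Multi-Compartment Conductance-Based Models of Thalamic Interneurons
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulator for detailed compartmental models of local GABAergic
    interneurons of the dorsal lateral geniculate nucleus (dLGN). Provides a
    branched-cable Crank-Nicolson integrator with Hodgkin-Huxley style sodium
    and delayed-rectifier potassium channels, a hyperpolarization-activated
    cation current (Ih), low-threshold (T-type) and high-threshold (L-type)
    calcium channels with Goldman-Hodgkin-Katz flux, calcium-activated
    potassium (I_AHP) and nonspecific cation (I_CAN) currents, a
    leaky-integrator intracellular calcium pool, somatodendritic channel
    density rules, a surrogate-morphology generator with SWC import/export,
    current-clamp, voltage-clamp and GABAergic synaptic-barrage protocols,
    and feature analysis (spike detection, I/O curves, sag, burst and rebound
    classification, Boltzmann and bell-curve fitting of Ih kinetics). Ships
    two parameterizations (P1 and P2) adapted to recordings from two mouse
    dLGN interneurons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
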