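Package: spreadnet
Title: Discrete-Time Markov-Chain Spreading Models on Complex Networks
    with Output-Feedback Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and stabilization of discrete-time Markov-chain
    susceptible-infected-susceptible (SIS) spreading processes on complex
    networks. Provides a preferential-attachment network generator, the
    contact-based per-node infection dynamics with heterogeneous recovery,
    infection and contact parameters, per-node stability certificates
    (Gerschgorin row and column conditions and the spectral-radius
    condition) that identify which nodes must be monitored and controlled,
    and linear output-feedback control laws that stabilize the extinction
    state. Includes configuration-driven experiment drivers that reproduce
    endemic, zero-dynamics and closed-loop feedback scenarios at
    configurable network scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
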