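Package: iontunnel
Title: Quantum Tunneling of Ions Through Closed Voltage-Gated Channels
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Steady-state biophysical model of ion permeation through the
    closed gates of voltage-gated channels by quantum tunneling. Provides
    Eckart-barrier transmission probabilities (exact and approximate, in log
    space), single-channel and areal quantum conductances, classical and
    quantum Goldman-Hodgkin-Katz membrane-potential solvers for Na+/K+/Ca2+
    on the inner-hair-cell basolateral membrane, and the "quantum synapse"
    Bernoulli cascade giving the probability of action-potential induction
    between demyelinated neurons. Includes parameter-sweep engines, scenario
    files, a validation report of worked examples, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, yaml, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
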