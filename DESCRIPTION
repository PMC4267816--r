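Package: fmnet
Title: Spiking Network Models of FM Sweep Rate and Direction Selectivity
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic fixed-step simulator for minimal spiking networks of
    frequency-modulated (FM) sweep selectivity in the auditory system. Neurons
    are reduced difference-equation (map) models with a fast voltage variable
    and a slow adaptation variable; synapses are first-order kinetic
    conductances with integer-step transmission delays. The package builds and
    analyses three canonical circuits: asymmetric sideband inhibition
    (fast-pass rate selectivity and direction preference), two-input
    delay-line facilitation (band-pass coincidence detection), and duration
    tuning by early onset inhibition plus delayed integrative excitation
    (coincidence and anti-coincidence regimes). Direction selectivity of the
    sideband circuit can be trained with spike-timing-dependent plasticity
    under conservation of total incoming synaptic weight, and selectivity is
    quantified with rate-response scans, a direction selectivity index (DSI)
    and an inhibitory-weight asymmetry index (ASY).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr,
    optparse
Config/testthat/edition: 3
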