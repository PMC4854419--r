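Package: rivalrymem
Title: Mutual-Inhibition Circuit Models of Perceptual Rivalry and Rivalry
    Memory
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis toolkit for the canonical cortical
    circuit model of perceptual rivalry: mutually inhibiting neuronal pools
    with local (adaptation-like) and nonlocal (synaptic-depression-like)
    fatigue and a square-root gain. Covers static rivalry, intermittent
    rivalry under pulsed stimulation such as the ambiguous quartet apparent
    motion illusion, and rivalry memory maintained by nonspecific background
    activity. Includes fixed-point and bifurcation analysis of the reduced
    two-pool circuit, a conductance-style spiking counterpart, percept
    readout into dominance durations, and a mixed-effects Cox
    proportional-hazards stage for dominance-duration survival analysis with
    right censoring, subject screening, and a residual proportionality check.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    survival,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
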