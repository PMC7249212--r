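Package: firevac
Title: Wildfire Perimeter Spread Simulation and Fire-Safe Animal Evacuation Routing
Version: 0.1.0
Authors@R:
    person("FRAC", "Tools", email = "frac-tools@example.org", role = c("aut", "cre"))
Description: Discrete-time wildfire perimeter simulation on raster landscapes
    (Huygens-style front expansion driven by fuel class, vegetation humidity,
    wind and slope), coupled to a time-dependent evacuation router on an
    oriented, traffic-weighted road graph. The router computes the optimal
    evacuation route for animals (OPERA): the minimum-node path whose every
    junction is still untouched by the fire at the moment the evacuating
    vehicle reaches it, solved by a label-setting search with an exhaustive
    oracle for verification. Includes traffic-flow speed statistics
    (time-mean, space-mean, 85th-percentile and modal speeds), buffer-based
    farm exposure classification, seeded synthetic-landscape generators, and
    a command-line interface wiring the full pipeline together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
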