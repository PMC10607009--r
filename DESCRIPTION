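Package: mothwind
Title: Lagrangian Simulation and Forecast Verification of Windborne Moth
    Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting and verifying the overseas wind-borne
    migration of nocturnal moths such as the fall armyworm (Spodoptera
    frugiperda).  Provides a terrain-following (z*) gridded meteorology
    container with space-time interpolation, synthetic weather scenario
    generators (uniform flow, low-level jet with Ekman-like turning,
    nocturnal temperature profiles, constant/linear/parabolic diffusivity),
    release scheduling from source-area polygons, a Lagrangian particle
    integrator with dusk ascent, leeward self-propulsion, vertical
    random-walk diffusion with gradient drift and a temperature ceiling,
    trap-arrival detection by great-circle proximity, and the
    hitting-ratio evaluation protocol for daily migration predictions
    against pheromone-trap catch series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
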