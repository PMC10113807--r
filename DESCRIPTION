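Package: ecoreserv
Title: Ecological Reservoir Computing with Delay Embeddings and Simplex Projection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Reservoir computing where the reservoir is an ecological
    dynamical system. Reservoir dynamics are given either by an explicit
    two-species Lotka-Volterra map, by a random recurrent network (echo
    state network baseline), or by empirical or synthetic time series via
    time-delay embedding and simplex projection (empirical dynamic
    modelling). Includes species/time/space multiplexing, ridge-regression
    readouts with open- and closed-loop operation, benchmark task
    generators (Lorenz, NARMA, Mackey-Glass, uniform random input),
    diagnostics (echo state property, forgetting curves, memory capacity,
    NMSE), synthetic ecological data generators, and a data-processing
    pipeline for temperature-driven population experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    mgcv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    deSolve,
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
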