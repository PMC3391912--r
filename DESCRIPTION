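Package: termitory
Title: Seasonal Lattice Simulation of Subterranean Termite Territories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stochastic cellular-automaton model of foraging-territory
    formation in subterranean termites under seasonal climate forcing.
    Territories of N founding pairs grow on a random-landscape lattice
    during summers of duration T and contract to a fraction sigma of
    their size each winter, with distally weighted reactivation of
    growth. The package provides the synchronous-update simulator, a
    replicate sweep runner over the (T, sigma, N) parameter grid,
    rank-size territory distributions with a two-segment semi-log slope
    estimator, and a Kohonen self-organizing map with Ward clustering
    for partitioning the parameter plane by slope regime. A small
    command-line interface drives configurable simulation, sweep and
    analysis runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    class,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
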