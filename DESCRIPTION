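Package: myolattice
Title: Spatially Explicit Half-Sarcomere Model of Crossbridge Cycling and
    Muscle Work Loops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Stochastic spatially explicit simulation of a muscle half
    sarcomere as a three-dimensional spring lattice: thick and thin
    filaments of series linear springs, two-spring (torsional plus linear)
    myosin heads cycling through a three-state kinetic scheme by Monte
    Carlo transitions, an exponential titin spring, and a prescribed
    radial myofilament lattice spacing. Simulates isometric twitch and
    tetanus responses and cyclic work loops at physiological strain
    amplitudes and frequencies, with parameter sweeps over phase of
    activation, lattice spacing, crossbridge stiffness and titin
    stiffness, to quantify how nanometre-scale differences in lattice
    spacing modulate net mechanical work.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
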