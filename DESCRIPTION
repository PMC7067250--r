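Package: flexnets
Title: Modeling and Analysis of Flexible Nets with Uncertain Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build, validate and analyse Flexible Nets, a Petri-net-like
    formalism in which places and transitions are connected through event
    and intensity handlers carrying linear-inequality blocks.  Uncertain
    stoichiometry, uncertain initial markings and uncertain kinetic rates
    are expressed as constraint blocks rather than point values.  The
    package executes event nets discretely (enabling, firing, reachability
    graphs and observation-consistent marking sets), assembles the linear
    state-equation systems of event nets, intensity nets and their
    combination, transcribes timed dynamics over a grid into linear or
    convex-quadratic programs, and runs receding-horizon (model predictive
    control) optimisation on top of the transcription.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    quadprog,
    yaml,
    jsonlite,
    tibble,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
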