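Package: vasoadapt
Title: Biphasic Microvascular Blood Flow and Inverse Prediction of Vessel
    Diameter Changes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates blood flow in microvascular networks as a biphasic
    fluid (plasma plus individually tracked red blood cells, with the
    Fahraeus-Lindqvist effect and phase separation at divergent
    bifurcations), and solves the corresponding inverse problem: given a
    prescribed flow increase in an activated vessel set, it computes the
    vessel diameter changes that reach the target while minimally
    disturbing flow elsewhere, using time-averaged fields, representative
    transmissibilities and an adjoint-based gradient descent. Includes a
    hexagonal capillary-lattice generator, tabular network I/O, scenario
    drivers and post-processing utilities.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
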