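Package: hhsym
Title: Symmetry Analysis of Hodgkin-Huxley Membrane Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the symmetry structure of the
    Hodgkin-Huxley conductance model of excitable membranes. Implements
    the classical voltage-dependent gating rate functions, fixed-step
    simulation of current-clamp and voltage-clamp protocols, a synthetic
    voltage-clamp trace generator, numerical and symbolic Lie brackets of
    the model's symmetry generators with structure-constant estimation,
    trajectory-level audits of gate boundedness, time-translation and
    conductance-scaling invariance, and integer gating-exponent inference
    under the rotation-group representation constraint, including a
    fractional-exponent symmetry-breaking diagnostic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
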