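Package: esnparse
Title: Reservoir Computing Models of Real-Time Thematic Role Assignment
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates sentence comprehension in the fronto-striatal system
    with an echo state network: a fixed, sparse, random recurrent network of
    leaky-integrator neurons (a model of prefrontal cortex) is driven
    word-by-word by closed-class words and semantic-word markers, and a
    linear readout (a model of striatal neurons) trained by ridge regression
    predicts, in real time, the thematic role of every semantic word in a
    sentence. Includes construction-grammar corpus generators (a
    462-construction grammar, a 45-construction fixture with two-sentence
    discourse segments, and an extended redundant grammar), word-level
    meaning decoding and error measures, cross-validation experiment
    harnesses, parameter sweeps, and readout-change traces that serve as a
    P600 analog.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
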