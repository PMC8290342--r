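Package: silkdeg
Title: Enzymatic Degradation Kinetics of Silk Fibroin Sponges
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits time-course mass-loss data for lyophilized silk fibroin
    sponges to a Michaelis-Menten rate law and its modified first-order limit
    by weighted nonlinear least squares, discriminates between the two model
    classes from the shape of the error surface over the Michaelis constant,
    and quantifies rate-constant uncertainty by Gaussian parametric
    Monte-Carlo resampling. Includes a synthetic study generator that emulates
    continuous (repeated weighing) and discrete (destructive sampling)
    degradation experiment designs, per-day one-sample t-tests against zero
    remaining mass, and an end-to-end analysis pipeline with tabular reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
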