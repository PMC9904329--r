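Package: hidenum
Title: Numerosity Estimation of Hidden Objects Behind Occluders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how observers estimate the number of objects
    hidden behind occluders. Implements procedural stimulus construction
    (game boards with mesh or bar occluders, night skies with Brownian-noise
    clouds and stars), trial-design enumeration for a five-experiment
    numerosity battery, synthetic observers that generate two-alternative
    forced-choice, confidence, and direct-estimation responses, cumulative
    Gaussian psychometric and inverse-Gaussian confidence curve fitting
    (point of subjective equality, lapse rate, confidence amplitude), and a
    Bayesian ideal observer that infers the total object count from the
    visible count through a hypergeometric urn likelihood combined with
    Gaussian priors over either the total or the hidden count, compared by
    BIC and relative model weights.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
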