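Package: nashnets
Title: Networks Consistent with an Assumed Nash Equilibrium of Binary Network Games
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Inverse analysis of binary-strategy network games. Given an
    assumed Nash equilibrium (a 0/1 strategy per player), the package
    verifies whether a candidate interaction network realizes that
    equilibrium under the majority game, the minority game, or the
    best-shot public goods game; counts the acceptable labeled networks
    exactly (closed forms via inclusion-exclusion where they exist,
    exhaustive enumeration otherwise); enumerates the acceptable set with
    edge-count histograms; and estimates each acceptable network's
    probability of occurrence by an absorbing random edge-toggle walk over
    the space of all labeled graphs. Includes plain-text graph/profile IO
    and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
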