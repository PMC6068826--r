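Package: stairsafe
Title: Dynamic-Stability Design of Stair Step Depth for Primary Schools
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stampede-prevention analysis of school staircases.
    Generates reproducible synthetic cohorts of primary-school students and
    timed stair-descent trials, computes pause-corrected descent speeds and
    foot-clearance summaries, applies an inverted-pendulum model of dynamic
    stability during stair descent to derive closed-form lower and upper
    bounds on safe step depth, combines Student-t interval estimates of the
    model parameters into a design range, and projects the range over a
    building's service life using linear anthropometric growth trends.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
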