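Package: skillret
Title: Retention of Intermittently Used Skills Under Exponential Forgetting
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stochastic renewal-process model of the loss of a collectively
    held skill that is practised at irregular intervals. Between uses the
    number of group members able to deploy the skill decays exponentially
    with forgetting time tau; each use resets the pool to its maximum; the
    skill is permanently lost when an interval without use exceeds the
    maximum unused-retention time tau*log(eta_max). Provides a Monte-Carlo
    engine over truncated-normal use intervals, a closed-form solution via
    the normal tail probability, cross-validation between the two,
    parameter-space sweeps with loss/retention classification and boundary
    extraction, and estimation of the forgetting time from skill-retention
    decay data by nonlinear least squares.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    stats,
    parallel,
    minpack.lm,
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
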