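Package: ccxover
Title: Case-Crossover Analysis Robust to Within-Subject Exposure Dependency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimators for case-crossover studies when an individual's
    exposure history is autocorrelated (for example cyclic drug regimens).
    Implements a weighting method that estimates the relative probability of
    exposure at the case period from discordant person-time and uses it to
    weight the Greenland conditional likelihood, removing the bias that
    standard conditional logistic regression incurs under within-subject
    exposure dependency.  Also provides the standard conditional logistic
    estimator, the matched Mantel-Haenszel odds ratio (optionally stratified
    by a binary time-varying confounder), the Vines-Farrington
    permutation-probability estimator, percentile bootstrap confidence
    intervals, a bias diagnostic comparing the Mantel-Haenszel and
    conditional logistic odds ratios, a deterministic cyclic-exposure
    simulator of a stationary dynamic population, and tools to collapse
    daily exposure histories into longer analysis periods under several
    exposure definitions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
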