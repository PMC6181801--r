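Package: predstat
Title: Prediction Strategies and Functional Network Statistics for
    Statistical Learning Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studies of probabilistic sequence learning and
    decision strategy. Defines zero- and first-order Markov stimulus
    sources, generates and selects stimulus sequences by Kullback-Leibler
    divergence to the source, scores prediction responses with a
    minimum-overlap Performance Index normalized by a random-guess
    baseline, and locates responders on the probability-matching versus
    maximization continuum via an integral-curve-difference strategy
    index. On the imaging side it provides component selection against
    tissue maps, nuisance cleaning and GLM beta estimation for component
    timecourses, functional network connectivity (Fisher z), robust
    skipped correlation with percentile-bootstrap confidence intervals,
    and Steiger's test for dependent correlations. A synthetic-data
    module generates responder agents and HRF-convolved component
    timecourses with planted effects so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
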