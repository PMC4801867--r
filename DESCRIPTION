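Package: stopsignal
Title: Bayes-Optimal Decision Making and Behavioral Analysis for the
    Stop-Signal Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling and analysing inhibitory control in the
    stop-signal task. Implements a Bayes-optimal ideal observer that
    maintains posterior beliefs about the go stimulus and a possibly
    onsetting stop signal, solves the resulting belief-state Markov
    decision process by backward induction on a discretized belief grid,
    and simulates cohorts of model subjects across go-discriminability
    conditions. Also provides the classical independent race model as a
    baseline and as a synthetic cohort generator with known ground truth,
    behavioral measures (reaction-time summaries, error rates, inhibition
    functions, smoothing-spline SSRT estimation), and one-sided paired
    t / Wilcoxon condition comparisons over per-subject summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
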