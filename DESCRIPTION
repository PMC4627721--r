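Package: normatt
Title: Attention-Modulated Divisive Normalization Models of Interocular
    Suppression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates and fits a population model of interocular
    suppression in which a monocular target is masked by a competitor
    shown to the other eye. Neural responses arise from divisive
    normalization of monocular excitatory drives combined with
    stimulus-driven and goal-driven attentional gain fields; behavioral
    sensitivity (d-prime) is read out from the neuron best tuned to the
    target. Includes descriptive Naka-Rushton psychometric fitting with
    bootstrap tests for contrast-gain versus response-gain changes,
    seven-parameter least-squares model fitting with bootstrap confidence
    intervals, cross-validated and BIC-based comparison of feature-specific
    versus eye-specific attention variants, Hessian-rank identifiability
    checks, and a synthetic trial-level psychophysics data generator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
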