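# normatt

Attention-modulated divisive normalization models of interocular
suppression, with the full psychophysics analysis pipeline around them.

## The problem

In interocular suppression a perfectly visible target shown to one eye
becomes hard to discriminate the moment a salient *competitor* appears in
the other eye. Two neural mechanisms plausibly drive this: divisive
normalization (the competitor joins the normalization pool of neurons
responding to the target, across eyes) and stimulus-driven attention (the
competitor's abrupt onset grabs attentional gain away from the target).
They leave different fingerprints on the psychometric function
d'(c): attention with a small spatial footprint scales the asymptote
(*response gain*), while a wide footprint and interocular normalization
shift the curve along the contrast axis (*contrast gain*).

`normatt` is for psychophysicists and computational neuroscientists who
want to simulate, fit and compare these mechanisms on trial-level
orientation-discrimination data.

## The model

Two monocular populations of neurons, indexed by receptive-field center
`x` and preferred orientation `theta`, respond as

    R_L(x,t) = A_x A_v E_L^n / (S_L + w_I S_R + sigma^n)

with excitatory drive `E` (RF Gaussian 1.5 deg SD, orientation tuning 48
deg FWHM), suppressive drive `S` = suppression kernel convolved with
`A_x A_v E^n` (spatial width 6 deg shrinking with orientation offset,
tau = 20 deg), stimulus-driven attention `A_x = w_x a_theta a_x' + 1`
(von Mises orientation profile, k = 3; Gaussian spatial profile with
extent equal to competitor size and magnitude/extent trade-off `p`),
goal-driven attention `A_v` centered on the target orientation, and
interocular normalization weight `w_I` (optionally directional,
`w_LR`/`w_RL`). Behavioral sensitivity is d' = R(target neuron)/sigma_n.
The stimulus-driven field comes in a feature-specific (FS) and an
eye-specific (ES) variant — distinguishable behaviorally by a *split*
competitor whose center and surround go to different eyes.

Descriptive analysis uses Naka-Rushton psychometric fits
`d'(c) = d'_m c^n / (c^n + c50^n)` with bootstrap tests on `d'_m`
(response gain) and `c50` (contrast gain); model-based analysis is
seven-parameter least squares with bootstrap CIs, cross-validated
FS-vs-ES comparison, BIC, and a Hessian-rank identifiability check.

## A worked example

```r
library(normatt)

trials <- generate_trials(study_design(seed = 1), variant = "FS")
nakarushton(trials)
#> Naka-Rushton descriptive fit (group_average, shared exponent)
#>  observer condition  d_m    c50    n c50_at_bound
#>     group      none 2.64 0.0131 1.81        FALSE
#>     group     small 1.30 0.0123 1.81        FALSE
#>     group    medium 2.29 0.0266 1.81        FALSE
#>     group     large 2.64 0.0330 1.81        FALSE
#>     group     split 2.49 0.0319 1.81        FALSE
#> R-squared: group 0.975

fit <- normatt(trials, variant = "FS", n_starts = 5)
summary(fit)
#> normalization/attention model fit (FS variant)
#>   45 cells, 7 free parameters, R-squared = 96.7%
#>        n    sigma      w_I      w_x      w_v        p  sigma_n
#> 1.924000 0.060970 0.363500 4.652000 4.887000 0.364400 0.005196
#> stimulus-driven gain at the target neuron: (none 1.00, small 0.20, medium 0.34, large 0.57, split 0.57)
#> goal-driven gain at the target neuron: 1.97
```

Reading the output: the small competitor leaves `c50` nearly alone but
halves the asymptote (`d_m` 2.64 to 1.30) — a response-gain change — while
the large and split competitors shift `c50` (0.013 to 0.033) with the
asymptote roughly preserved — contrast-gain changes. In the mechanistic
fit, the parenthesized gains are the stimulus-driven attentional gain at
the neuron tuned to the target per condition (1 means no modulation), and
the goal-driven gain is the task-driven boost at the same neuron.

Other entry points: `bootstrap_gain_tests()` (significance of `d_m`/`c50`
changes), `bootstrap_params()` (parameter CIs), `crossval_compare()` and
`bic_compare()` (FS vs ES), `hessian_rank()` (identifiability),
`population_response()` / `predict_psychometric()` (forward model),
`read_trials()` / `write_trials()` / `write_results()` (plain-text I/O).

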