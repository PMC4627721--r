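#' Model parameters
#'
#' Container for the seven free parameters of the normalization/attention
#' model plus its fixed constants. `n` is the exponent of the neural
#' contrast-response function, `sigma` the semi-saturation constant (in
#' units of excitatory drive; see the package vignette for the unit
#' convention), `w_I` the interocular normalization weight, `w_x` and `w_v`
#' the magnitudes of stimulus-driven and goal-driven attentional
#' modulation, `p` the trade-off between the magnitude and the spatial
#' extent of the stimulus-driven attentional gain, and `sigma_n` the
#' magnitude of the behavioral noise linking the target neuron's response
#' to d-prime.
#'
#' The interocular weight may be made directional: `w_LR` weights the
#' suppression the left-eye drive exerts on the right-eye population and
#' `w_RL` the reverse. Both default to `w_I`.
#'
#' Fixed constants: `sigma_sx = 6` (spatial width of the suppressive field
#' for iso-orientation stimuli), `tau = 20` (orientation selectivity of
#' surround suppression), `k = 3` (feature-attention concentration, a 40
#' degree FWHM), `goal_sigma_ax = 60` and `goal_p = 0` (spatial profile of
#' goal-driven attention).
#'
#' @param n,sigma,w_I,w_x,w_v,p,sigma_n free parameters (see above). For
#'   the compound attention variant `w_x` may have length 2:
#'   `c(feature, eye)` magnitudes.
#' @param w_LR,w_RL optional directional interocular weights.
#' @return an object of class `"model_params"` (a named list).
#' @export
model_params <- function(n, sigma, w_I, w_x, w_v, p, sigma_n,
                         w_LR = w_I, w_RL = w_I) {
  stopifnot(n > 0, sigma > 0, sigma_n > 0, w_I >= 0, w_LR >= 0, w_RL >= 0,
            all(w_x >= 0), w_v >= 0, p >= 0, p <= 1,
            length(w_x) %in% c(1L, 2L))
  structure(list(n = n, sigma = sigma, w_I = w_I, w_x = w_x, w_v = w_v,
                 p = p, sigma_n = sigma_n, w_LR = w_LR, w_RL = w_RL,
                 sigma_sx = 6, tau = 20, k = 3,
                 goal_sigma_ax = 60, goal_p = 0),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("normalization/attention model parameters:\n")
  v <- c(n = x$n, sigma = x$sigma, w_I = x$w_I,
         w_x = if (length(x$w_x) == 2) NA else x$w_x,
         w_v = x$w_v, p = x$p, sigma_n = x$sigma_n)
  print(signif(v, 4))
  if (length(x$w_x) == 2)
    cat(sprintf("  w_x (compound): feature %.4g, eye %.4g\n",
                x$w_x[1], x$w_x[2]))
  if (x$w_LR != x$w_I || x$w_RL != x$w_I)
    cat(sprintf("  directional: w_LR = %.4g, w_RL = %.4g\n", x$w_LR, x$w_RL))
  invisible(x)
}

#' Reference parameter sets for the simulator
#'
#' Study-condition parameter sets used by the synthetic-data generator:
#' the group-level feature-specific best fit, and four observer-level sets
#' whose interocular weights span the heterogeneity seen across real
#' observers (w_I from near 0 to nearly 4). `sigma` and `sigma_n` are
#' expressed in the package's drive-unit convention, calibrated so that
#' the no-competitor psychometric function has a semi-saturation contrast
#' of about 1% and an asymptote of d-prime about 2.5 (see the vignette).
#'
#' @param observer `"group"` or one of `"S1"`..`"S4"`.
#' @return a [model_params()] object.
#' @export
reference_params <- function(observer = c("group", "S1", "S2", "S3", "S4")) {
  observer <- match.arg(observer)
  tab <- list(
    group = list(n = 1.95, w_I = 0.67, w_x = 4.24, w_v = 5.03, p = 0.13),
    S1 = list(n = 2.15, w_I = 0.01, w_x = 4.62, w_v = 4.65, p = 0.26),
    S2 = list(n = 2.21, w_I = 1.08, w_x = 4.50, w_v = 5.03, p = 0.20),
    S3 = list(n = 1.67, w_I = 1.15, w_x = 2.96, w_v = 5.02, p = 0.24),
    S4 = list(n = 2.22, w_I = 3.81, w_x = 4.89, w_v = 5.03, p = 0.12))[[observer]]
  model_params(n = tab$n, sigma = CALIBRATED_SIGMA, w_I = tab$w_I,
               w_x = tab$w_x, w_v = tab$w_v, p = tab$p,
               sigma_n = CALIBRATED_SIGMA_N)
}

## Calibrated in the package's drive units (vignette, "Units and
## calibration"): chosen once so the no-competitor curve at the group
## parameters has c50 = 1% contrast and asymptotic d-prime = 2.5.
CALIBRATED_SIGMA <- 0.0496
CALIBRATED_SIGMA_N <- 0.00542
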