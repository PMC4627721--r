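#' Attentional profiles
#'
#' `feature_profile()` is the feature-based (orientation) attention
#' profile: a von Mises bump over orientation, rescaled to run from -0.5
#' (at 90 degrees from the attended orientation) to +0.5 (at it):
#' `exp(k * (cos(2 * dtheta) - 1)) - 0.5`. With the default concentration
#' `k = 3` the unshifted bump `exp(k(cos 2x - 1))` has a 40 degree FWHM.
#'
#' `spatial_profile()` is the spatial attention profile
#' `sigma_ax^(-p) / sqrt(2*pi) * exp(-(x - x_a)^2 / (2 sigma_ax^2))`.
#' The exponent `p` trades magnitude against spatial extent: with `p = 1`
#' the profile has fixed volume (its integral over `x` does not depend on
#' `sigma_ax`); with `p = 0` the peak is independent of the extent.
#'
#' @param delta_theta orientation difference(s) from the attended
#'   orientation, degrees.
#' @param k concentration of feature-based attention.
#' @param x position(s), degrees.
#' @param x_a attended position, degrees.
#' @param sigma_ax spatial extent of attention, degrees (> 0).
#' @param p magnitude/extent trade-off exponent in `[0, 1]`.
#' @return numeric vector of profile values.
#' @export
feature_profile <- function(delta_theta, k = 3) {
  stopifnot(k > 0)
  exp(k * (cos(2 * delta_theta * pi / 180) - 1)) - 0.5
}

#' @rdname feature_profile
#' @export
spatial_profile <- function(x, x_a = 0, sigma_ax, p) {
  if (!is.numeric(sigma_ax) || sigma_ax <= 0)
    stop("'sigma_ax' must be positive; got ", sigma_ax)
  stopifnot(p >= 0, p <= 1)
  sigma_ax^(-p) / sqrt(2 * pi) * exp(-(x - x_a)^2 / (2 * sigma_ax^2))
}

unit_field <- function(grid) {
  one <- matrix(1, length(grid$x), length(grid$theta))
  list(left = one, right = one)
}

check_gain <- function(field, what) {
  m <- min(field$left, field$right)
  if (m < -1e-9)
    stop(sprintf("%s attentional gain is negative (min %.4g); ", what, m),
         "the attention parameters violate the non-negativity constraint")
  field
}

## Eye-specific deviation fields: each competitor component of (outer)
## width d presented to eye e adds +w_x * a_x(x; sigma_ax = d, p) to that
## eye's gain and subtracts the same amount from the other eye, uniformly
## over orientation. Deviations from multiple components add.
es_deviation <- function(components, grid, w_x, p) {
  nt <- length(grid$theta)
  dev <- list(left = matrix(0, length(grid$x), nt),
              right = matrix(0, length(grid$x), nt))
  comp <- components[components$role == "competitor", , drop = FALSE]
  for (r in seq_len(nrow(comp))) {
    ax <- spatial_profile(grid$x, 0, comp$width[r], p)
    d <- w_x * (ax %o% rep(1, nt))
    e <- comp$eye[r]
    dev[[e]] <- dev[[e]] + d
    dev[[other_eye(e)]] <- dev[[other_eye(e)]] - d
  }
  dev
}

#' Stimulus-driven attentional gain field
#'
#' The gain field induced by the abrupt onset of the competitor, with
#' baseline 1. In the feature-specific (`"FS"`) variant the gain is
#' selective for the competitor's orientation and fused spatial extent and
#' is identical in the two eyes, so the split and large competitors induce
#' exactly the same field. In the eye-specific (`"ES"`) variant there is
#' no orientation selectivity: the gain is raised in the eye that receives
#' a competitor component and lowered by the same amount in the other eye.
#' The `"compound"` variant adds the two deviations (and takes
#' `w_x = c(feature, eye)` magnitudes).
#'
#' @param components component data frame from [expand_condition()].
#' @param grid a [neuron_grid()].
#' @param w_x attentional magnitude(s) (length 2 for `"compound"`).
#' @param p magnitude/extent trade-off exponent.
#' @param variant `"FS"`, `"ES"` or `"compound"`.
#' @param check error if the resulting gain is negative anywhere
#'   (constraint violation).
#' @return list of gain matrices `left` and `right`.
#' @export
stimulus_attention <- function(components, grid, w_x, p,
                               variant = c("FS", "ES", "compound"),
                               check = TRUE) {
  variant <- match.arg(variant)
  stopifnot(all(w_x >= 0),
            length(w_x) == (if (variant == "compound") 2L else 1L))
  comp <- components[components$role == "competitor", , drop = FALSE]
  if (nrow(comp) == 0L) return(unit_field(grid))
  field <- switch(variant,
    FS = {
      sig <- fused_competitor_width(components)
      ath <- feature_profile(wrap_ori(grid$theta - comp$orientation[1]),
                             k = 3)
      ax <- spatial_profile(grid$x, 0, sig, p)
      A <- 1 + w_x * (ax %o% ath)
      list(left = A, right = A)
    },
    ES = {
      dev <- es_deviation(components, grid, w_x, p)
      list(left = 1 + dev$left, right = 1 + dev$right)
    },
    compound = {
      fs <- stimulus_attention(components, grid, w_x[1], p, "FS",
                               check = FALSE)
      dev <- es_deviation(components, grid, w_x[2], p)
      list(left = fs$left + dev$left, right = fs$right + dev$right)
    })
  if (check) check_gain(field, "stimulus-driven") else field
}

#' Goal-driven attentional gain field
#'
#' Task-driven feature-based attention to the target orientation: gains
#' above 1 for neurons tuned near the target orientation and below 1 near
#' the orthogonal (competitor) orientation, spread very widely over space
#' (Gaussian spatial profile with `sigma_ax = 60` degrees, `p = 0`).
#' Identical for the two eyes and across all competitor conditions.
#'
#' @param grid a [neuron_grid()].
#' @param w_v goal-driven attentional magnitude.
#' @param target_orientation attended orientation, degrees.
#' @param check error if the gain is negative anywhere.
#' @return list of gain matrices `left` and `right` (shared).
#' @export
goal_attention <- function(grid, w_v, target_orientation = TARGET_ORI,
                           check = TRUE) {
  stopifnot(w_v >= 0)
  ath <- feature_profile(wrap_ori(grid$theta - target_orientation), k = 3)
  ax <- spatial_profile(grid$x, 0, 60, 0)
  A <- 1 + w_v * (ax %o% ath)
  field <- list(left = A, right = A)
  if (check) check_gain(field, "goal-driven") else field
}
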