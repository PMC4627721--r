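## Excitatory drive of the monocular populations.

## Spatial overlap of the RF Gaussian (SD rf_sd, centered at each grid x)
## with a component's aperture interval(s), normalized so that an aperture
## covering the whole field gives 1.
aperture_overlap <- function(x, comp, rf_sd) {
  iv <- component_intervals(comp)
  ov <- numeric(length(x))
  for (r in seq_len(nrow(iv)))
    ov <- ov + (stats::pnorm((iv[r, 2] - x) / rf_sd) -
                stats::pnorm((iv[r, 1] - x) / rf_sd))
  ov
}

## Circular-Gaussian orientation tuning, peak 1, differences wrapped to
## (-90, 90].
orientation_tuning <- function(theta, ori, tuning_sd) {
  d <- wrap_ori(theta - ori)
  exp(-d^2 / (2 * tuning_sd^2))
}

#' Excitatory drive fields
#'
#' Computes the excitatory drive of each monocular population over the
#' neuron grid: for every component presented to an eye, its contrast
#' times the spatial overlap of the receptive field with the aperture
#' times the orientation tuning, summed over components. Drive is linear
#' in contrast, zero for an unstimulated eye, and independent of the grid
#' step.
#'
#' @param components component data frame from [expand_condition()].
#' @param grid a [neuron_grid()].
#' @return a list with matrices `left` and `right`
#'   (`length(grid$x)` by `length(grid$theta)`).
#' @export
excitatory_drive <- function(components, grid) {
  empty <- matrix(0, length(grid$x), length(grid$theta))
  out <- list(left = empty, right = empty)
  if (is.null(components) || nrow(components) == 0L) return(out)
  for (r in seq_len(nrow(components))) {
    comp <- components[r, ]
    ov <- aperture_overlap(grid$x, comp, grid$rf_sd)
    tun <- orientation_tuning(grid$theta, comp$orientation, grid$tuning_sd)
    out[[comp$eye]] <- out[[comp$eye]] + comp$contrast * (ov %o% tun)
  }
  out
}
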