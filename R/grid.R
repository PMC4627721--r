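#' Monocular neuron grid
#'
#' The simulated population is a 2-D array of monocular neurons per eye,
#' indexed by receptive-field center `x` (degrees of visual angle, spanning
#' -20 to 20) and preferred orientation `theta` (degrees, circular with
#' period 180). The orientation axis is placed so that the 45 degree target
#' orientation always falls on a grid node (and 135 whenever `dtheta`
#' divides 90); d-prime is read out from the neuron exactly tuned to the
#' target. The spatial excitatory field of each neuron is a Gaussian with
#' 1.5 degree SD and the orientation tuning a circular Gaussian with 48
#' degree FWHM.
#'
#' @param dx spatial step in degrees; `x_range/dx` must be whole numbers.
#' @param dtheta orientation step in degrees; must divide 180.
#' @param x_range extent of receptive-field centers (degrees).
#' @param rf_sd SD of the spatial excitatory field (degrees).
#' @param tuning_fwhm FWHM of the orientation tuning curve (degrees).
#' @return an object of class `"neuron_grid"`.
#' @export
neuron_grid <- function(dx = 0.25, dtheta = 1, x_range = c(-20, 20),
                        rf_sd = 1.5, tuning_fwhm = 48) {
  stopifnot(dx > 0, dtheta > 0, 180 %% dtheta == 0, x_range[1] < 0,
            x_range[2] > 0)
  nneg <- round(-x_range[1] / dx)
  npos <- round(x_range[2] / dx)
  x <- seq(-nneg, npos) * dx   # always contains 0
  ntheta <- as.integer(round(180 / dtheta))
  theta <- sort(((seq_len(ntheta) - 1L) * dtheta + 45) %% 180)
  structure(list(x = x, theta = theta, dx = dx, dtheta = dtheta,
                 rf_sd = rf_sd,
                 tuning_sd = tuning_fwhm / (2 * sqrt(2 * log(2)))),
            class = "neuron_grid")
}

#' @export
print.neuron_grid <- function(x, ...) {
  cat(sprintf(
    "neuron grid: %d RF centers in [%g, %g] deg (dx = %g), %d orientations (dtheta = %g)\n",
    length(x$x), min(x$x), max(x$x), x$dx, length(x$theta), x$dtheta))
  invisible(x)
}

## Wrap orientation differences to (-90, 90] (period 180).
wrap_ori <- function(d) {
  d <- (d + 90) %% 180 - 90
  d[d == -90] <- 90
  d
}

grid_index <- function(grid, x0, theta0) {
  i <- which.min(abs(grid$x - x0))
  j <- which.min(abs(wrap_ori(grid$theta - theta0)))
  c(i, j)
}
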