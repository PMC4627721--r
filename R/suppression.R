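#' Suppression kernel
#'
#' The kernel that pools the attention-modulated excitatory drive over
#' space and orientation to form the suppressive drive:
#' `K(dx, dtheta) = exp(-dx^2 / (2 sigma(dtheta)^2))` with
#' `sigma(dtheta) = sigma_sx * exp(-|dtheta| / tau)` and orientation
#' differences wrapped to `[0, 90]`. At zero spatial offset the kernel is
#' 1 for every orientation difference (suppression within the receptive
#' field is untuned for orientation), while the spatial reach of surround
#' suppression shrinks as the orientation difference grows (surround
#' suppression is orientation selective). The kernel is used exactly as
#' written, unnormalized with peak 1; its mass is absorbed by the
#' semi-saturation constant `sigma`.
#'
#' @param dx spatial offset(s), degrees.
#' @param dtheta orientation offset(s), degrees.
#' @param sigma_sx spatial width for iso-orientation stimuli (degrees).
#' @param tau orientation selectivity of surround suppression (degrees).
#' @return kernel values, recycled over `dx` and `dtheta`.
#' @export
suppression_kernel <- function(dx, dtheta, sigma_sx = 6, tau = 20) {
  stopifnot(sigma_sx > 0, tau > 0)
  s <- sigma_sx * exp(-abs(wrap_ori(dtheta)) / tau)
  exp(-dx^2 / (2 * s^2))
}

## Kernel weights for the discrete convolution: the spatial factor is
## averaged over each grid cell (exact Gaussian integral over
## [dx - h, dx + h], h = step/2) rather than sampled pointwise, so the
## quadrature stays accurate even where the kernel narrows below the grid
## step (large orientation offsets); the pointwise kernel is recovered as
## the step shrinks.
kernel_weight <- function(dx, dtheta, step, sigma_sx = 6, tau = 20) {
  stopifnot(sigma_sx > 0, tau > 0)
  s <- sigma_sx * exp(-abs(wrap_ori(dtheta)) / tau)
  h <- step / 2
  s * sqrt(2 * pi) *
    (stats::pnorm((dx + h) / s) - stats::pnorm((dx - h) / s)) / step
}

## Kernel weight matrices for convolution over a grid. x offsets are laid
## out in FFT order over L = 2*nx - 1 samples (exact linear convolution
## with zero padding beyond the grid); theta offsets are circular with
## period 180.
kernel_fft_matrix <- function(grid, sigma_sx = 6, tau = 20) {
  nx <- length(grid$x)
  nt <- length(grid$theta)
  L <- 2L * nx - 1L
  offx <- c(0:(nx - 1L), -(nx - 1L):-1L) * grid$dx
  offt <- (seq_len(nt) - 1L) * grid$dtheta
  outer(offx, offt, kernel_weight, step = grid$dx, sigma_sx = sigma_sx,
        tau = tau)
}

#' Suppressive drive
#'
#' Convolves the attention-modulated excitatory drive
#' `M = A_x * A_v * E^n` with the suppression kernel: linear in `x` (zero
#' padding beyond the grid) and circular in orientation (period 180
#' degrees). The sum is weighted by the grid cell area `dx * dtheta`, so
#' the result approximates the continuous integral and is stable under
#' grid refinement. Computed by FFT; exact linear/circular convolution.
#'
#' @param modulated matrix `A_x * A_v * E^n` over the grid.
#' @param grid a [neuron_grid()].
#' @param sigma_sx,tau kernel constants, see [suppression_kernel()].
#' @return matrix of suppressive drive over the grid.
#' @export
suppressive_drive <- function(modulated, grid, sigma_sx = 6, tau = 20) {
  nx <- length(grid$x)
  nt <- length(grid$theta)
  if (!is.matrix(modulated) || nrow(modulated) != nx ||
      ncol(modulated) != nt)
    stop("'modulated' must be a ", nx, " x ", nt,
         " matrix matching the grid")
  K <- kernel_fft_matrix(grid, sigma_sx, tau)
  L <- nrow(K)
  M <- rbind(modulated, matrix(0, L - nx, nt))
  S <- Re(stats::fft(stats::fft(M) * stats::fft(K), inverse = TRUE)) /
    (L * nt)
  S[seq_len(nx), , drop = FALSE] * grid$dx * grid$dtheta
}

## Readout weights: one row of the convolution, i.e. the kernel centered
## on the neuron at (x0, theta0), times the cell area. sum(W * M) equals
## suppressive_drive(M, grid)[at (x0, theta0)].
readout_weights <- function(grid, x0 = 0, theta0 = TARGET_ORI,
                            sigma_sx = 6, tau = 20) {
  outer(x0 - grid$x, wrap_ori(theta0 - grid$theta), kernel_weight,
        step = grid$dx, sigma_sx = sigma_sx, tau = tau) *
    grid$dx * grid$dtheta
}
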