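#' Gabor spatial scale from frequency bandwidth
#'
#' The receptive-field envelope sigma consistent with a radial peak
#' frequency `fs` (cycles/pixel) and an octave bandwidth `B`, taking one
#' standard deviation of the amplitude spectrum as the cut-off frequency:
#' `sigma = (2^B + 1) / ((2^B - 1) * 2 * pi * fs)`. The spectrum of a Gabor
#' with envelope sigma has spectral standard deviation `1 / (2*pi*sigma)`;
#' placing the octave band edges `fs * 2^(+/-B/2)`... at one spectral sd
#' from fs yields this relation. With `fs = 0.13` and `sigma = 5.12` the
#' implied bandwidth is about 0.70 octaves.
#'
#' @param fs Peak frequency, cycles/pixel.
#' @param B Bandwidth, octaves.
#' @return Envelope standard deviation, pixels.
#' @export
gabor_sigma <- function(fs, B) {
  (2^B + 1) / ((2^B - 1) * 2 * pi * fs)
}

#' Octave bandwidth implied by a Gabor sigma (inverse of [gabor_sigma()])
#' @param fs Peak frequency, cycles/pixel.
#' @param sigma Envelope standard deviation, pixels.
#' @return Bandwidth, octaves.
#' @export
gabor_bandwidth <- function(fs, sigma) {
  x <- 2 * pi * fs * sigma
  log2((x + 1) / (x - 1))
}

#' Complex Gabor kernel
#'
#' `g(xi, eta) = A * exp(-(xi^2 + eta^2) / (2 sigma^2)) *
#' exp(j * (2*pi*fs*(cos(theta) xi + sin(theta) eta) + psi))`, normalized to
#' unit energy (`A = 1 / (sqrt(pi) * sigma)`) and corrected to zero mean by
#' subtracting a scaled copy of the Gaussian envelope, so the response to
#' any constant image is exactly zero.
#'
#' @param theta Preferred orientation, radians.
#' @param sigma Envelope standard deviation, pixels.
#' @param fs Radial peak frequency, cycles/pixel.
#' @param psi Phase, radians.
#' @param half_width Kernel half-width; default `ceiling(3 * sigma)`. A
#'   warning is raised when the support is smaller than `6 sigma + 1`.
#' @return A complex `(2*half_width+1)` square matrix; rows are xi,
#'   columns eta.
#' @export
gabor_kernel <- function(theta, sigma, fs, psi = 0, half_width = NULL) {
  if (sigma <= 0 || fs <= 0) stop("sigma and fs must be positive")
  if (is.null(half_width)) half_width <- ceiling(3 * sigma)
  if (2 * half_width + 1 < 6 * sigma + 1)
    warning("kernel support smaller than 6*sigma + 1")
  ax <- seq(-half_width, half_width)
  xi <- matrix(ax, length(ax), length(ax))
  eta <- t(xi)
  env <- exp(-(xi^2 + eta^2) / (2 * sigma^2))
  carrier <- exp(1i * (2 * pi * fs * (cos(theta) * xi + sin(theta) * eta) + psi))
  g <- env * carrier / (sqrt(pi) * sigma)
  g - env * (sum(g) / sum(env))
}

#' Bank of oriented complex Gabor kernels
#'
#' `N` orientations uniformly sampling \[0, pi).
#'
#' @param N Number of orientations.
#' @param sigma Envelope standard deviation, pixels.
#' @param fs Peak frequency, cycles/pixel.
#' @param half_width Kernel half-width passed to [gabor_kernel()].
#' @return List of complex kernels; the orientations are attached as
#'   attribute `theta`.
#' @export
gabor_bank <- function(N = 12, sigma = 5.12, fs = 0.13, half_width = NULL) {
  thetas <- (seq_len(N) - 1) * pi / N
  bank <- lapply(thetas, gabor_kernel, sigma = sigma, fs = fs,
                 half_width = half_width)
  attr(bank, "theta") <- thetas
  bank
}
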