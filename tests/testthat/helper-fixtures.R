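# Small shared geometries; built once per test run.

tiny_mapping <- function() lp_mapping(64, 64, R = 24, rho0 = 2)

test_mapping <- function() lp_mapping(192, 192, R = 61, rho0 = 2)

noiseless_config <- function(...) {
  model_config(noise_v1 = 0, noise_mt = 0, ...)
}

# Sub-pixel circular shift of each row across columns (FFT phase ramp);
# independent of the package's internal helpers.
shift_columns <- function(x, d) {
  m <- ncol(x)
  f <- c(0, seq_len(m - 1)); f[f > m / 2] <- f[f > m / 2] - m
  ph <- exp(-2i * pi * f * d / m)
  t(Re(stats::mvfft(stats::mvfft(t(x)) * ph, inverse = TRUE)) / m)
}

# Centered pixel-coordinate grids (rows = y, cols = x), package convention.
.row_col_grid <- function(n) {
  ax <- seq_len(n) - (n + 1) / 2
  list(x = matrix(ax, n, n, byrow = TRUE), y = matrix(ax, n, n))
}
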