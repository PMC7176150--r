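#' Stimulus specification for disparity-corrugation stereograms
#'
#' Describes one pink-noise stereogram carrying an oblique sinusoidal
#' disparity corrugation inside an annular window. Geometry is specified in
#' degrees of visual angle and converted to pixels through
#' `pixels_per_degree`.
#'
#' @param frequency Corrugation spatial frequency, cycles/degree.
#' @param amplitude Peak-to-trough disparity, arcmin.
#' @param tilt Corrugation tilt, 45 or 135 degrees (any angle accepted).
#' @param inner,outer Annulus inner and outer radius, degrees eccentricity;
#'   `inner = 0` gives a disk.
#' @param edge Width of the cosinusoidal window edges, degrees.
#' @param field_radius Radius of the modelled visual field, degrees.
#' @param pixels_per_degree Display scale. The laboratory display this
#'   emulates had a 0.311 mm dot pitch viewed at 45 cm, i.e. about 23.8
#'   px/degree by the small-angle approximation.
#' @param size Image side in pixels; default `2 * field_radius *
#'   pixels_per_degree`, rounded.
#' @param seed Integer seed for the noise carrier.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(frequency, amplitude, tilt = 45,
                          inner = 0, outer = 21, edge = 1,
                          field_radius = 21, pixels_per_degree = 23.8,
                          size = NULL, seed = 1L) {
  stopifnot(frequency > 0, amplitude >= 0)
  if (!(inner >= 0 && inner < outer && outer <= field_radius))
    stop("need 0 <= inner < outer <= field_radius")
  if (is.null(size))
    size <- 2 * round(field_radius * pixels_per_degree)
  spec <- list(frequency = frequency, amplitude = amplitude, tilt = tilt,
               inner = inner, outer = outer, edge = edge,
               field_radius = field_radius,
               pixels_per_degree = pixels_per_degree,
               size = as.integer(size), seed = as.integer(seed))
  class(spec) <- "stimulus_spec"
  spec
}

# Evaluate an RNG-consuming expression under a temporary seed, restoring the
# caller's RNG state afterwards.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' 1/f pink-noise image
#'
#' Generates an isotropic noise image whose amplitude spectrum falls as 1/f
#' with radial spatial frequency (random phases from the seeded generator).
#' The field is standardized to zero mean and unit variance and then mapped
#' affinely into \[0, 1\] with the mean fixed at mid-gray (0.5): the gain is
#' the largest that keeps every pixel in range.
#'
#' @param size Image side, pixels (>= 8).
#' @param seed Integer seed; same seed, same image, bit for bit.
#' @return A `size x size` matrix in \[0, 1\].
#' @export
pink_noise <- function(size, seed = 1L) {
  if (size < 8) stop("size must be >= 8")
  z <- .with_seed(seed, {
    wn <- matrix(stats::rnorm(size * size), size, size)
    f1 <- c(0, seq_len(size - 1)) / size
    f1 <- pmin(f1, 1 - f1)            # signed frequency magnitude
    fr <- sqrt(outer(f1^2, f1^2, `+`))
    amp <- 1 / fr
    amp[1, 1] <- 0                    # DC handled explicitly
    Re(stats::fft(stats::fft(wn) * amp, inverse = TRUE)) / (size * size)
  })
  z <- z - mean(z)
  z <- z / stats::sd(z)
  0.5 + z * (0.5 / max(abs(z)))
}

# Raised-cosine annular window, radius in degrees.
.annular_window <- function(rho_deg, inner, outer, edge) {
  w <- numeric(length(rho_deg))
  e_in <- if (inner > 0) min(edge, (outer - inner) / 2) else 0
  e_out <- min(edge, (outer - inner) / 2)
  flat <- rho_deg >= inner + e_in & rho_deg <= outer - e_out
  w[flat] <- 1
  if (e_in > 0) {
    ramp <- rho_deg >= inner & rho_deg < inner + e_in
    w[ramp] <- 0.5 - 0.5 * cos(pi * (rho_deg[ramp] - inner) / e_in)
  }
  if (e_out > 0) {
    ramp <- rho_deg > outer - e_out & rho_deg <= outer
    w[ramp] <- 0.5 + 0.5 * cos(pi * (rho_deg[ramp] - (outer - e_out)) / e_out)
  }
  w
}

#' Disparity corrugation map
#'
#' The ground-truth horizontal disparity field: a sinusoid of the requested
#' spatial frequency modulated along the axis orthogonal to the tilt
#' direction, with amplitude `amplitude / 2` (half the peak-to-trough
#' value), windowed by the annulus with raised-cosine edges. Tilt 45 and
#' tilt 135 maps are mirror images about the vertical axis.
#'
#' A warning (not an error) is raised when the annulus cannot contain half
#' a cycle of the corrugation: such stimuli are still generated, since the
#' inability of a small central window to hold a full corrugation cycle is
#' itself part of the phenomenology under study.
#'
#' @param spec A [stimulus_spec()].
#' @return A `size x size` matrix of horizontal disparity, arcmin.
#' @export
corrugation_map <- function(spec) {
  n <- spec$size
  ppd <- spec$pixels_per_degree
  ax <- (seq_len(n) - (n + 1) / 2) / ppd
  xd <- matrix(ax, n, n, byrow = TRUE)
  yd <- matrix(ax, n, n)
  if (2 * spec$outer * spec$frequency < 0.5)
    warning("annulus holds less than half a corrugation cycle")
  alpha <- (180 - spec$tilt) * pi / 180   # modulation axis
  phase <- 2 * pi * spec$frequency * (xd * cos(alpha) + yd * sin(alpha))
  rho <- sqrt(xd^2 + yd^2)
  (spec$amplitude / 2) * sin(phase) *
    matrix(.annular_window(rho, spec$inner, spec$outer, spec$edge), n, n)
}

# Catmull-Rom cubic resampling of each row of `img` at horizontal positions
# shifted by `shift` (a matrix of per-pixel column shifts). Columns are
# clamped at the borders.
.resample_rows <- function(img, shift) {
  n <- nrow(img); m <- ncol(img)
  pos <- matrix(rep(seq_len(m), each = n), n, m) + shift
  i1 <- floor(pos)
  t <- pos - i1
  cl <- function(k) pmin(pmax(k, 1L), m)
  ridx <- rep(seq_len(n), m)
  gather <- function(k) matrix(img[cbind(ridx, as.integer(cl(i1 + k)))], n, m)
  p0 <- gather(-1L); p1 <- gather(0L); p2 <- gather(1L); p3 <- gather(2L)
  t2 <- t * t; t3 <- t2 * t
  0.5 * ((2 * p1) + (-p0 + p2) * t +
         (2 * p0 - 5 * p1 + 4 * p2 - p3) * t2 +
         (-p0 + 3 * p1 - 3 * p2 + p3) * t3)
}

#' Render a stereo pair from a noise carrier and a disparity map
#'
#' Applies the disparity as symmetric horizontal half-shifts: the left eye
#' samples the carrier displaced by +d/2 and the right eye by -d/2 (cubic
#' Catmull-Rom interpolation along rows), keeping the cyclopean geometry
#' centered. A zero disparity map reproduces the carrier bit-exactly in
#' both eyes.
#'
#' @param noise Carrier image (matrix), e.g. from [pink_noise()].
#' @param disparity_map Horizontal disparity in arcmin, same shape.
#' @param spec The [stimulus_spec()] (supplies `pixels_per_degree`).
#' @param max_disparity_deg Sanity bound on |disparity|, degrees.
#' @return A `stereo_pair`: list with `left`, `right`,
#'   `ground_truth_disparity` (arcmin) and `spec`.
#' @export
render_stereo <- function(noise, disparity_map, spec,
                          max_disparity_deg = 2) {
  if (!all(dim(noise) == dim(disparity_map)))
    stop("noise and disparity map shapes differ")
  if (max(abs(disparity_map)) > max_disparity_deg * 60)
    stop("disparity exceeds the sanity bound")
  shift_px <- disparity_map / 60 * spec$pixels_per_degree
  pair <- list(left = .resample_rows(noise, shift_px / 2),
               right = .resample_rows(noise, -shift_px / 2),
               ground_truth_disparity = disparity_map,
               spec = spec)
  class(pair) <- "stereo_pair"
  pair
}

#' Generate a complete corrugation stereogram
#'
#' Convenience wrapper: seeded pink-noise carrier, corrugation map, stereo
#' rendering.
#'
#' @param spec A [stimulus_spec()].
#' @return A `stereo_pair`.
#' @export
make_stimulus <- function(spec) {
  noise <- pink_noise(spec$size, seed = spec$seed)
  dmap <- corrugation_map(spec)
  render_stereo(noise, dmap, spec)
}
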