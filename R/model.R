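#' Configuration of the cortical disparity model
#'
#' Default values are the reference parameterization of the full-scale
#' simulated observer: Gabor peak frequency `fs = 0.13` cycles/cortical
#' pixel with envelope `sigma = 5.12` cortical pixels (about 0.70 octaves),
#' `N = 12` orientations, `K = 5` disparity channels spanning the cortical
#' disparity range `D = +/-1.52` pixels, V1 static nonlinearity exponent
#' 0.5, MT spatial pooling `sigma_pool = 3.66` cortical pixels with
#' exponential gain `lambda = 0.65`, and uniform neural noise at 34% (V1)
#' and 18% (MT) of the local average activity.
#'
#' @param fs Gabor radial peak frequency, cycles/cortical pixel.
#' @param sigma Gabor envelope sd, cortical pixels.
#' @param N Number of orientations.
#' @param K Number of disparity channels (odd, so zero disparity is
#'   represented); channels are evenly spaced on `[-D, D]`.
#' @param D Cortical disparity range, cortical pixels.
#' @param exponent V1 static nonlinearity power.
#' @param eps Divisive-normalization floor.
#' @param sigma_pool MT spatial pooling sd, cortical pixels.
#' @param lambda Gain of the MT exponential nonlinearity.
#' @param noise_v1,noise_mt Noise amplitude as a fraction of the local
#'   average activity at each stage (0 disables). The fractions are stated
#'   for the reference full-scale cortical grid; see `noise_ref_units`.
#' @param noise_ref_units Unit count of the reference cortical grid
#'   (default `318 * 494`, the full-scale geometry). Observers built on a
#'   grid of `n` units apply the noise fractions scaled by
#'   `sqrt(n / noise_ref_units)` (capped at 1), so that the aggregate
#'   noise power reaching the decoded map is invariant to the simulation
#'   grid size: with i.i.d. noise per unit, map-level noise scales as
#'   `frac / sqrt(n)`. Set to `NULL` to disable the correction and apply
#'   the fractions per unit as stated.
#' @param variant One of `"LP"` (log-polar, default), `"LP2S"` (log-polar
#'   plus a second coarser scale), `"noLP"` (uniform downsampling front
#'   end), `"noLP2S"`.
#' @param downsample Downsampling factor of the `noLP` front end; default
#'   `round(sqrt(CR))` of the mapping it replaces, so the unit count is
#'   comparable.
#' @param normalize_decode Logical; see [decode_disparity()].
#' @param calibrate_decode Logical; estimate the decoder's population gain
#'   once at observer construction (see [decode_disparity()]).
#' @return A list of class `model_config`.
#' @export
model_config <- function(fs = 0.13, sigma = 5.12, N = 12, K = 5, D = 1.52,
                         exponent = 0.5, eps = 1e-9,
                         sigma_pool = 3.66, lambda = 0.65,
                         noise_v1 = 0.34, noise_mt = 0.18,
                         noise_ref_units = 318 * 494,
                         variant = c("LP", "LP2S", "noLP", "noLP2S"),
                         downsample = NULL,
                         normalize_decode = TRUE,
                         calibrate_decode = TRUE) {
  variant <- match.arg(variant)
  if (K %% 2 != 1) stop("K must be odd so that zero disparity is represented")
  cfg <- list(fs = fs, sigma = sigma, N = N, K = K, D = D,
              exponent = exponent, eps = eps,
              sigma_pool = sigma_pool, lambda = lambda,
              noise_v1 = noise_v1, noise_mt = noise_mt,
              noise_ref_units = noise_ref_units,
              variant = variant, downsample = downsample,
              normalize_decode = normalize_decode,
              calibrate_decode = calibrate_decode)
  class(cfg) <- "model_config"
  cfg
}

# ---- cortical-domain convolution -------------------------------------------
# The cortical sheet is an annulus: circular along eta (sectors), mirrored
# along xi (rings). The noLP variant lives on the Cartesian grid and mirrors
# both axes.

.pad_cortical <- function(img, hw, mirror_cols) {
  n <- nrow(img)
  if (hw >= n || (mirror_cols && hw >= ncol(img)))
    stop("cortical grid too small for the kernel support")
  P <- rbind(img[hw:1, , drop = FALSE], img,
             img[n:(n - hw + 1), , drop = FALSE])
  if (mirror_cols) {
    m <- ncol(P)
    P <- cbind(P[, hw:1, drop = FALSE], P, P[, m:(m - hw + 1), drop = FALSE])
  }
  P
}

# FFT of a kernel centered at the origin of a (pr x pc) padded grid.
.kernel_fft <- function(kernel, pr, pc) {
  hw <- (nrow(kernel) - 1) / 2
  K <- matrix(0 + 0i, pr, pc)
  idx_r <- ((-hw):(hw)) %% pr + 1
  idx_c <- ((-hw):(hw)) %% pc + 1
  K[idx_r, idx_c] <- kernel[]
  stats::fft(K)
}

.conv_padded <- function(img_fft, kfft, hw, nu, nv, mirror_cols) {
  out <- stats::fft(img_fft * kfft, inverse = TRUE) / length(img_fft)
  rows <- (hw + 1):(hw + nu)
  cols <- if (mirror_cols) (hw + 1):(hw + nv) else seq_len(nv)
  out[rows, cols]
}

# ---- observer construction -------------------------------------------------

#' Build a simulated cortical observer
#'
#' Precomputes everything a trial needs: the log-polar forward operator (or
#' the uniform-downsampling front end for the `noLP` variants), the FFTs of
#' the oriented Gabor bank and of the MT pooling kernel on the padded
#' cortical grid, the disparity channels and their interocular phase
#' offsets (`delta_psi = 2 * pi * fs * d`), and the annular region masks.
#'
#' @param mapping An [lp_mapping()] describing the front end (its Cartesian
#'   dimensions set the stimulus size).
#' @param config A [model_config()].
#' @param field_deg Field radius in degrees mapped onto `rho_max`.
#' @return An object of class `disparity_observer`.
#' @export
disparity_observer <- function(mapping, config = model_config(),
                               field_deg = 21) {
  obs <- list(mapping = mapping, config = config, field_deg = field_deg,
              ppd = mapping$rho_max / field_deg)
  lp <- config$variant %in% c("LP", "LP2S")
  if (lp) {
    obs$nu <- mapping$R
    obs$nv <- mapping$S
    obs$mirror_cols <- FALSE
    .forward_op(mapping)  # warm the cache
  } else {
    ds <- config$downsample
    if (is.null(ds)) ds <- max(1L, round(sqrt(mapping$CR)))
    obs$ds <- as.integer(ds)
    obs$nu <- floor(mapping$Nr / ds)
    obs$nv <- floor(mapping$Nc / ds)
    obs$mirror_cols <- TRUE
  }
  d_set <- seq(-config$D, config$D, length.out = config$K)
  obs$d_set <- d_set
  # phase channel of a cell preferring disparity d: delta_psi = -2*pi*fs*d
  # (sign fixed so that the decoded component matches the applied shift)
  obs$delta_psi <- -2 * pi * config$fs * d_set
  # N tuning directions over the full circle; the Gabor at theta + pi is
  # the conjugate of the one at theta, so only N/2 kernels are convolved
  if (config$N %% 2 != 0) stop("N must be even")
  obs$theta <- (seq_len(config$N) - 1) * 2 * pi / config$N

  hw <- ceiling(3 * config$sigma)
  obs$hw <- hw
  pr <- obs$nu + 2 * hw
  pc <- if (obs$mirror_cols) obs$nv + 2 * hw else obs$nv
  half_bank <- lapply(obs$theta[seq_len(config$N / 2)], gabor_kernel,
                      sigma = config$sigma, fs = config$fs, half_width = hw)
  obs$bank_fft <- lapply(half_bank, .kernel_fft, pr = pr, pc = pc)
  obs$pdim <- c(pr, pc)

  hwp <- ceiling(3 * config$sigma_pool)
  obs$hwp <- hwp
  gx <- seq(-hwp, hwp)
  gk <- exp(-outer(gx^2, gx^2, `+`) / (2 * config$sigma_pool^2))
  gk <- gk / sum(gk)
  ppr <- obs$nu + 2 * hwp
  ppc <- if (obs$mirror_cols) obs$nv + 2 * hwp else obs$nv
  obs$pool_fft <- .kernel_fft(gk, ppr, ppc)
  obs$ppdim <- c(ppr, ppc)

  # node-center geometry for the cortical-domain decision template
  if (lp) {
    u <- rep(seq_len(obs$nu) - 1L, times = obs$nv)
    v <- rep(seq_len(obs$nv) - 1L, each = obs$nu)
    rho <- mapping$rho0 * mapping$a^(u + 0.5)
    th <- (v + 0.5) / mapping$q
    obs$node_x <- rho * cos(th)
    obs$node_y <- rho * sin(th)
    obs$node_cos <- cos(th)
    obs$node_sin <- sin(th)
    obs$node_ecc <- rho / obs$ppd
  } else {
    ds <- obs$ds
    xs <- (rep(seq_len(obs$nv), each = obs$nu) - (obs$nv + 1) / 2) * ds
    ys <- (rep(seq_len(obs$nu), times = obs$nv) - (obs$nu + 1) / 2) * ds
    obs$node_x <- xs
    obs$node_y <- ys
    # horizontal disparity lives on the eta (column) axis of the uniform
    # grid: d_x units = +d_eta (see retinal_disparity)
    obs$node_cos <- rep(0, obs$nu * obs$nv)
    obs$node_sin <- rep(-1, obs$nu * obs$nv)
    obs$node_ecc <- sqrt(xs^2 + ys^2) / obs$ppd
  }
  nsc <- 1
  if (!is.null(config$noise_ref_units))
    nsc <- min(1, sqrt(obs$nu * obs$nv / config$noise_ref_units))
  obs$noise_v1_eff <- config$noise_v1 * nsc
  obs$noise_mt_eff <- config$noise_mt * nsc
  class(obs) <- "disparity_observer"
  obs$masks <- region_masks(obs)
  obs$decode_gain <- 1
  if (isTRUE(config$calibrate_decode))
    obs$decode_gain <- .decode_gain(obs)
  obs
}

# Circular sub-pixel shift of each row across columns (the eta axis).
.shift_cols <- function(x, d) {
  m <- ncol(x)
  f <- c(0, seq_len(m - 1)); f[f > m / 2] <- f[f > m / 2] - m
  ph <- exp(-2i * pi * f * d / m)
  t(Re(stats::mvfft(stats::mvfft(t(x)) * ph, inverse = TRUE)) / m)
}

# One-time decoder gain calibration: the population read-out of the
# raised-cosine channel tuning underestimates a uniform shift by a fixed,
# nearly disparity-independent factor. A deterministic textured cortical
# image is shifted by a known sub-channel amount along eta and pushed
# through the noiseless V1/MT stack; the median decoded value fixes the
# gain. Stimulus-independent: computed once per observer geometry.
.decode_gain <- function(obs) {
  cfg <- obs$config
  n <- max(obs$nu, obs$nv, 8)
  tex <- pink_noise(n, seed = 20L)[seq_len(obs$nu), seq_len(obs$nv)]
  d_cal <- 0.5 * cfg$D
  E <- .v1_energy(obs, tex, .shift_cols(tex, d_cal))
  Emt <- .mt_flat(obs, .normalize_v1_flat(E, cfg$exponent, cfg$eps))
  dim(Emt) <- c(obs$nu, obs$nv, 2, cfg$K)
  raw <- decode_disparity(obs, Emt, normalize = TRUE)
  g <- stats::median(raw$d_eta) / d_cal
  if (!is.finite(g) || g <= 0) g <- 1
  g
}

# Front-end transform of a Cartesian image for this observer.
.front_end <- function(obs, img) {
  if (obs$config$variant %in% c("LP", "LP2S")) {
    to_cortical(img, obs$mapping)
  } else {
    ds <- obs$ds
    nr <- obs$nu * ds; nc <- obs$nv * ds
    x <- img[seq_len(nr), seq_len(nc)]
    dim(x) <- c(ds, obs$nu, ds, obs$nv)
    y <- colMeans(x, dims = 1)            # [nu, ds, nv]
    colMeans(aperm(y, c(2, 1, 3)), dims = 1)
  }
}

# ---- V1 stage ---------------------------------------------------------------

# Complex monocular responses of the Gabor bank (list over orientations).
.monocular_responses <- function(obs, cort) {
  P <- .pad_cortical(cort, obs$hw, obs$mirror_cols)
  Pf <- stats::fft(P)
  lapply(obs$bank_fft, .conv_padded, img_fft = Pf, hw = obs$hw,
         nu = obs$nu, nv = obs$nv, mirror_cols = obs$mirror_cols)
}

#' Binocular simple-cell responses
#'
#' Phase-shift binocular simple cells: the left and right receptive fields
#' share a center and orientation but differ in phase by
#' `delta_psi = psi_L - psi_R` (applied symmetrically, `psi_L = +delta_psi/2`,
#' `psi_R = -delta_psi/2`). The in-phase response is
#' `R = conv(L, S_L) + conv(R, S_R)` and the quadrature partner `Rq` comes
#' from the imaginary parts of the same complex Gabor responses.
#'
#' @param obs A [disparity_observer()].
#' @param left_c,right_c Cortical images of the two eyes (equal mapping).
#' @return Complex array `[nu, nv, N, K]`; its real part is `R`, its
#'   imaginary part `Rq`.
#' @export
simple_cells <- function(obs, left_c, right_c) {
  if (!all(dim(left_c) == dim(right_c)))
    stop("left/right cortical images differ in shape")
  cfg <- obs$config
  CL <- .monocular_responses(obs, left_c)
  CR <- .monocular_responses(obs, right_c)
  out <- array(0 + 0i, c(obs$nu, obs$nv, cfg$N, cfg$K))
  phl <- exp(1i * obs$delta_psi / 2)
  nh <- cfg$N / 2
  for (th in seq_len(cfg$N)) {
    cl <- if (th <= nh) CL[[th]] else Conj(CL[[th - nh]])
    cr <- if (th <= nh) CR[[th]] else Conj(CR[[th - nh]])
    for (k in seq_len(cfg$K)) {
      out[, , th, k] <- cl * phl[k] + cr * Conj(phl[k])
    }
  }
  out
}

#' Binocular energy of a quadrature pair
#'
#' `E = R^2 + Rq^2`: nonnegative and invariant to a common absolute phase
#' of the stimulus in the two eyes.
#'
#' @param R,Rq In-phase and quadrature simple-cell responses (any
#'   conformable arrays).
#' @return Array of binocular energies.
#' @export
complex_energy <- function(R, Rq) R^2 + Rq^2

# Fast path for the binocular energy: avoids materializing the complex
# simple-cell array. For each direction theta,
# E = |cl|^2 + |cr|^2 + 2 * Re(cl * Conj(cr) * exp(i * delta_psi)).
.v1_energy <- function(obs, left_c, right_c) {
  cfg <- obs$config
  CL <- .monocular_responses(obs, left_c)
  CR <- .monocular_responses(obs, right_c)
  nloc <- obs$nu * obs$nv
  E <- array(0, c(nloc, cfg$N, cfg$K))
  nh <- cfg$N / 2
  cosd <- cos(obs$delta_psi); sind <- sin(obs$delta_psi)
  for (th in seq_len(cfg$N)) {
    cl <- if (th <= nh) CL[[th]] else Conj(CL[[th - nh]])
    cr <- if (th <= nh) CR[[th]] else Conj(CR[[th - nh]])
    cross <- cl * Conj(cr)
    m2 <- as.numeric(Mod(cl)^2 + Mod(cr)^2)
    re <- as.numeric(Re(cross)); im <- as.numeric(Im(cross))
    for (k in seq_len(cfg$K))
      E[, th, k] <- m2 + 2 * (re * cosd[k] - im * sind[k])
  }
  pmax(E, 0)   # clip tiny negative values from roundoff
}

# Divisive normalization on the flat [nloc, N, K] layout.
.normalize_v1_flat <- function(E, exponent, eps) {
  Ew <- E^exponent
  denom <- colSums(aperm(Ew, c(2, 1, 3)))   # [nloc, K], summed over N
  for (k in seq_len(dim(E)[3]))
    Ew[, , k] <- Ew[, , k] / (denom[, k] + eps)
  Ew
}

# Uniform noise on a flat [nloc, ...] activity array.
.noise_flat <- function(arr, frac) {
  if (frac <= 0) return(arr)
  d <- dim(arr)
  m <- rowMeans(matrix(arr, d[1]))
  arr <- arr + array(stats::runif(length(arr), -1, 1) * (frac * m), d)
  pmax(arr, 0)
}

# MT stage on the flat layout: orientation pooling is one matrix product
# per channel, spatial pooling one FFT convolution per (phi, channel).
.mt_flat <- function(obs, Ev1f) {
  cfg <- obs$config
  W <- cbind(cos(obs$theta), sin(obs$theta))   # phi = 0, pi/2
  out <- array(0, c(obs$nu * obs$nv, 2, cfg$K))
  for (k in seq_len(cfg$K)) {
    sk <- Ev1f[, , k] %*% W
    for (p in 1:2) {
      P <- .pad_cortical(matrix(sk[, p], obs$nu, obs$nv), obs$hwp,
                         obs$mirror_cols)
      pooled <- Re(.conv_padded(stats::fft(P), obs$pool_fft, obs$hwp,
                                obs$nu, obs$nv, obs$mirror_cols))
      out[, p, k] <- exp(cfg$lambda * as.numeric(pooled))
    }
  }
  out
}

#' Divisively normalized V1 responses
#'
#' Applies the static nonlinearity (power `exponent`) and divisive
#' normalization across orientations,
#' `E_V1(p, theta, d) = E^w / (sum_theta E^w + eps)`, removing confounds
#' from local contrast variations: away from the `eps` floor the V1
#' population is contrast invariant.
#'
#' @param E Energy array `[nu, nv, N, K]`.
#' @param exponent Nonlinearity power (0.5 by default).
#' @param eps Normalization floor.
#' @return Normalized array of the same shape.
#' @export
normalize_v1 <- function(E, exponent = 0.5, eps = 1e-9) {
  d <- dim(E)
  flat <- E
  dim(flat) <- c(d[1] * d[2], d[3], d[4])
  out <- .normalize_v1_flat(flat, exponent, eps)
  dim(out) <- d
  out
}

#' Add uniform population noise
#'
#' Zero-mean uniform noise whose half-width is `frac` times the local
#' average activity (the mean over all tuning dimensions at each cortical
#' location), clipped so activity stays nonnegative. Draws come from the
#' current RNG stream; seed the session (or the trial) for reproducibility.
#'
#' @param arr Activity array whose first two dimensions are cortical
#'   location.
#' @param frac Noise fraction; 0 returns the input unchanged.
#' @return Noisy activity array.
#' @export
add_population_noise <- function(arr, frac) {
  if (frac <= 0) return(arr)
  d <- dim(arr)
  nloc <- d[1] * d[2]
  m <- rowMeans(matrix(arr, nloc))
  noise <- matrix(stats::runif(length(arr), -1, 1), nloc) * (frac * m)
  pmax(array(arr + as.numeric(noise), d), 0)
}

# ---- MT stage ---------------------------------------------------------------

#' MT population response
#'
#' Pools V1 responses over space (Gaussian, `sigma_pool`) and orientation
#' (cosine weights `w_phi(theta) = cos(phi - theta)`), then applies the
#' exponential nonlinearity `F(s) = exp(lambda * s)`. Two tuning directions
#' `phi = 0` (xi component) and `phi = pi/2` (eta component) suffice to
#' encode the full vector disparity.
#'
#' @param obs A [disparity_observer()].
#' @param Ev1 Normalized V1 array `[nu, nv, N, K]` (noise already applied
#'   if desired).
#' @return MT array `[nu, nv, 2, K]`; `phi = 0` in slice 1, `phi = pi/2`
#'   in slice 2.
#' @export
mt_response <- function(obs, Ev1) {
  d <- dim(Ev1)
  flat <- Ev1
  dim(flat) <- c(d[1] * d[2], d[3], d[4])
  out <- .mt_flat(obs, flat)
  dim(out) <- c(d[1], d[2], 2, d[4])
  out
}

# ---- annular cue combination ------------------------------------------------

#' Annular region masks on the cortical grid
#'
#' Partitions the cortical grid into the foveal (0-3 deg), mid-peripheral
#' (3-9 deg) and far-peripheral (9-21 deg) rings of the protocol, by the
#' eccentricity of each node's receptive-field center.
#'
#' @param obs A [disparity_observer()] (or an `lp_mapping` plus `ppd`).
#' @param breaks_deg Region boundaries in degrees.
#' @param ppd Pixels per degree; taken from the observer when omitted.
#' @return Named list of logical `nu x nv` matrices (`fovea`, `mid`,
#'   `far`), a partition of the grid out to the last break.
#' @export
region_masks <- function(obs, breaks_deg = c(0, 3, 9, 21), ppd = NULL) {
  if (inherits(obs, "disparity_observer")) {
    lp <- obs$config$variant %in% c("LP", "LP2S")
    ppd <- obs$ppd
    if (lp) {
      ecc_px <- obs$mapping$rho0 * obs$mapping$a^(seq_len(obs$nu) - 0.5)
      ecc <- matrix(ecc_px / ppd, obs$nu, obs$nv)
    } else {
      ds <- obs$ds
      cx <- (obs$nv + 1) / 2; cy <- (obs$nu + 1) / 2
      xs <- (seq_len(obs$nv) - cx) * ds / ppd
      ys <- (seq_len(obs$nu) - cy) * ds / ppd
      ecc <- sqrt(outer(ys^2, xs^2, `+`))
    }
  } else stop("obs must be a disparity_observer")
  names_r <- c("fovea", "mid", "far")[seq_len(length(breaks_deg) - 1)]
  masks <- lapply(seq_len(length(breaks_deg) - 1), function(i)
    ecc >= breaks_deg[i] & ecc < breaks_deg[i + 1])
  names(masks) <- names_r
  masks
}

#' Combine MT activity across annular regions
#'
#' The full-field MT response is the sum of the responses restricted to
#' disjoint annular regions; for stimuli confined to one region only that
#' region's units carry activity, so combining masked responses over a
#' partition reproduces the unmasked response exactly.
#'
#' @param Emt MT array `[nu, nv, 2, K]`.
#' @param masks List of logical `nu x nv` masks; must be pairwise disjoint.
#' @return Combined MT array of the same shape.
#' @export
pool_annuli <- function(Emt, masks) {
  acc <- Reduce(`+`, lapply(masks, function(m) m + 0))
  if (any(acc > 1)) stop("region masks are not disjoint")
  d <- dim(Emt)
  out <- array(0, d)
  for (m in masks) {
    mm <- array(m, d)   # recycles over (phi, d) slices
    out <- out + Emt * mm
  }
  out
}

# ---- decoding ---------------------------------------------------------------

#' Decode the cortical disparity field from the MT population
#'
#' Linear population decoding: `d_xi(p) = sum_i d_i E_MT(p, 0, d_i)` and
#' `d_eta(p) = sum_i d_i E_MT(p, pi/2, d_i)`. With `normalize = TRUE`
#' (default) each component is divided by `sum_i E_MT(p, phi, d_i)` (a
#' population center of mass) and by the observer's decoder gain: the
#' center of mass of the broad raised-cosine channel tuning underestimates
#' the true shift by a fixed factor, which is measured once at observer
#' construction from known uniform shifts and divided out, so a uniform
#' shift of `d` cortical pixels decodes to about `d`. The unnormalized
#' form is the raw linear combination, whose scale carries the overall
#' population gain.
#'
#' @param obs A [disparity_observer()].
#' @param Emt MT array `[nu, nv, 2, K]`.
#' @param normalize Logical; defaults to the observer configuration.
#' @return List of class `disparity_field` with `d_xi`, `d_eta`
#'   (`nu x nv`, cortical pixels).
#' @export
decode_disparity <- function(obs, Emt,
                             normalize = obs$config$normalize_decode) {
  d <- obs$d_set
  dxi <- matrix(0, obs$nu, obs$nv)
  deta <- matrix(0, obs$nu, obs$nv)
  sxi <- matrix(0, obs$nu, obs$nv)
  seta <- matrix(0, obs$nu, obs$nv)
  for (k in seq_along(d)) {
    dxi <- dxi + d[k] * Emt[, , 1, k]
    deta <- deta + d[k] * Emt[, , 2, k]
    sxi <- sxi + Emt[, , 1, k]
    seta <- seta + Emt[, , 2, k]
  }
  if (normalize) {
    g <- if (is.null(obs$decode_gain)) 1 else obs$decode_gain
    dxi <- dxi / pmax(sxi, .Machine$double.eps) / g
    deta <- deta / pmax(seta, .Machine$double.eps) / g
  }
  structure(list(d_xi = dxi, d_eta = deta, obs_variant = obs$config$variant),
            class = "disparity_field")
}

#' Map a decoded cortical disparity field to retinal coordinates
#'
#' Each cortical component is backward-mapped with [to_retinal()] and the
#' local inverse Jacobian of the log-polar transform is applied: a scaling
#' by `rho0 * a^xi` (times `ln(a)` radially and `1/q` tangentially, which
#' the isotropy rule makes nearly equal) and a rotation by the polar angle.
#' For the `noLP` variants the front end is a uniform downsampling, so the
#' Jacobian is a constant scaling by the downsampling factor.
#'
#' @param obs A [disparity_observer()].
#' @param field A `disparity_field` from [decode_disparity()].
#' @return List with `dx`, `dy` in arcmin (positive x rightward), on the
#'   Cartesian pixel grid (LP variants) or the downsampled grid (noLP).
#' @export
retinal_disparity <- function(obs, field) {
  arcmin_per_px <- 60 / obs$ppd
  if (obs$config$variant %in% c("noLP", "noLP2S")) {
    # on the uniform grid the eta (column) axis is the horizontal image
    # axis and xi (rows) the vertical one
    return(list(dx = field$d_eta * obs$ds * arcmin_per_px,
                dy = field$d_xi * obs$ds * arcmin_per_px))
  }
  m <- obs$mapping
  bw <- .backward_geom(m)
  dxi_r <- as.numeric(bw$W %*% as.numeric(field$d_xi))
  deta_r <- as.numeric(bw$W %*% as.numeric(field$d_eta))
  ct <- cos(bw$theta); st <- sin(bw$theta)
  radial <- bw$rho * log(m$a) * dxi_r
  tangential <- bw$rho / m$q * deta_r
  dx <- matrix(0, m$Nr, m$Nc)
  dy <- matrix(0, m$Nr, m$Nc)
  dx[bw$ok] <- (ct * radial - st * tangential) * arcmin_per_px
  dy[bw$ok] <- (st * radial + ct * tangential) * arcmin_per_px
  list(dx = dx, dy = dy)
}

#' Tilt decision from a retinal disparity map
#'
#' Fourier-domain read-out of the corrugation tilt: the 2-D FFT magnitude
#' of the horizontal retinal disparity map is searched for its dominant
#' non-DC peak over quadrant-interior frequencies; the sign of the product
#' of its frequency components separates 45-degree from 135-degree
#' corrugations. In the discrimination task the corrugation frequency is
#' known to the observer (only the tilt is uncertain), so when `frequency`
#' is supplied the peak search is restricted to a one-octave annulus
#' around it, a matched-template read-out that ignores the slowly-varying
#' structure of the decoded map. A zero (or non-finite) map yields a
#' random guess from the current RNG stream.
#'
#' @param dx_map Horizontal retinal disparity map (matrix, rows = y).
#' @param frequency Optional known corrugation frequency, cycles/degree.
#' @param pixels_per_degree Required with `frequency`: the map's scale.
#' @return `"45"` or `"135"`.
#' @export
tilt_decision <- function(dx_map, frequency = NULL,
                          pixels_per_degree = NULL) {
  if (!all(is.finite(dx_map)) || max(abs(dx_map)) == 0)
    return(sample(c("45", "135"), 1))
  n <- nrow(dx_map); m <- ncol(dx_map)
  Fm <- Mod(stats::fft(dx_map))
  fy <- c(0, seq_len(n - 1)) / n; fy[fy > 0.5] <- fy[fy > 0.5] - 1
  fx <- c(0, seq_len(m - 1)) / m; fx[fx > 0.5] <- fx[fx > 0.5] - 1
  FY <- matrix(fy, n, m)
  FX <- matrix(fx, n, m, byrow = TRUE)
  valid <- FX > 0 & FY != 0          # half-plane, quadrant interior
  if (!is.null(frequency)) {
    if (is.null(pixels_per_degree))
      stop("pixels_per_degree is required with frequency")
    f_px <- frequency / pixels_per_degree
    fr <- sqrt(FX^2 + FY^2)
    band <- fr >= f_px / sqrt(2) & fr <= f_px * sqrt(2)
    if (any(valid & band)) valid <- valid & band
  }
  if (!any(valid)) return(sample(c("45", "135"), 1))
  Fm[!valid] <- -Inf
  peak <- arrayInd(which.max(Fm), dim(Fm))
  prod_sign <- FX[peak] * FY[peak]
  if (prod_sign == 0) return(sample(c("45", "135"), 1))
  if (prod_sign < 0) "45" else "135"
}

# ---- full pipeline ----------------------------------------------------------

# One scale of the V1 -> MT -> decode stack on a pair of front-end images.
# Works in the flat [nloc, ...] layout throughout.
.stack_one_scale <- function(obs, Lc, Rc) {
  cfg <- obs$config
  E <- .v1_energy(obs, Lc, Rc)
  Ev1 <- .normalize_v1_flat(E, cfg$exponent, cfg$eps)
  Ev1 <- .noise_flat(Ev1, obs$noise_v1_eff)
  Emt <- .mt_flat(obs, Ev1)
  Emt <- .noise_flat(Emt, obs$noise_mt_eff)
  dim(Emt) <- c(obs$nu, obs$nv, 2, cfg$K)
  decode_disparity(obs, Emt)
}

# Downsample a matrix by 2 (2x2 block mean, truncating odd edges).
.down2 <- function(x) {
  n <- 2 * (nrow(x) %/% 2); m <- 2 * (ncol(x) %/% 2)
  x <- x[seq_len(n), seq_len(m)]
  0.25 * (x[seq(1, n, 2), seq(1, m, 2)] + x[seq(2, n, 2), seq(1, m, 2)] +
          x[seq(1, n, 2), seq(2, m, 2)] + x[seq(2, n, 2), seq(2, m, 2)])
}

# Upsample by 2 with pixel replication, cropped/padded to (nu, nv).
.up2 <- function(x, nu, nv) {
  y <- x[rep(seq_len(nrow(x)), each = 2), rep(seq_len(ncol(x)), each = 2)]
  out <- matrix(0, nu, nv)
  r <- seq_len(min(nu, nrow(y))); c <- seq_len(min(nv, ncol(y)))
  out[r, c] <- y[r, c]
  out
}

#' Run the model on a stereo pair
#'
#' Full pipeline: front end (log-polar or uniform), V1 binocular energy
#' with divisive normalization and noise, MT pooling with noise, population
#' decoding, retinal back-mapping, and the tilt decision. The two-scale
#' variants run the V1/MT stack a second time on a 2x downsampled cortical
#' image and average the decoded fields (coarse disparities rescaled to
#' fine-grid pixels).
#'
#' @param obs A [disparity_observer()].
#' @param pair A `stereo_pair` from [make_stimulus()] or [render_stereo()],
#'   with images matching the observer's Cartesian dimensions.
#' @param seed Optional seed applied for the trial (noise and any guessing).
#' @return List with `decision` ("45"/"135"), the cortical `field`, and the
#'   retinal maps `dx`, `dy` (arcmin).
#' @export
model_trial <- function(obs, pair, seed = NULL) {
  run <- function() {
    Lc <- .front_end(obs, pair$left)
    Rc <- .front_end(obs, pair$right)
    field <- .stack_one_scale(obs, Lc, Rc)
    # cue-combination stage: only units in the stimulated annular region(s)
    # contribute to the model output
    smask <- .stimulus_mask(obs, pair$spec)
    if (!is.null(smask)) {
      field$d_xi <- field$d_xi * smask
      field$d_eta <- field$d_eta * smask
    }
    if (obs$config$variant %in% c("LP2S", "noLP2S")) {
      obs2 <- .rescale_observer(obs)
      f2 <- .stack_one_scale(obs2, .down2(Lc), .down2(Rc))
      field$d_xi <- 0.5 * (field$d_xi + 2 * .up2(f2$d_xi, obs$nu, obs$nv))
      field$d_eta <- 0.5 * (field$d_eta + 2 * .up2(f2$d_eta, obs$nu, obs$nv))
    }
    ret <- retinal_disparity(obs, field)
    freq <- if (!is.null(pair$spec$frequency)) pair$spec$frequency else NULL
    decision <- if (is.null(freq)) {
      tilt_decision(ret$dx)
    } else {
      inner <- if (is.null(pair$spec$inner)) 0 else pair$spec$inner
      outer <- if (is.null(pair$spec$outer)) obs$field_deg else
        pair$spec$outer
      tilt_decision_cortical(obs, field, freq, inner, outer)
    }
    list(decision = decision, field = field, dx = ret$dx, dy = ret$dy)
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}

#' Tilt decision from the decoded cortical disparity field
#'
#' The 2AFC read-out used by the simulated observer: the horizontal
#' disparity at each cortical node (in cortical-pixel units, i.e. in units
#' of the local disparity range) is projected onto the two candidate
#' corrugation templates — complex exponentials at the known frequency
#' along the 45- and 135-degree modulation axes, evaluated at the node
#' centers, restricted to the stimulated annulus — and the tilt with the
#' larger template magnitude wins. Working node-wise on the cortical grid
#' weights every neural unit equally (units carry comparable noise), so
#' the fovea contributes in proportion to its cortical over-representation
#' and regional reliabilities combine naturally for full-field stimuli.
#'
#' @param obs A [disparity_observer()].
#' @param field A `disparity_field` from [decode_disparity()].
#' @param frequency Corrugation frequency, cycles/degree.
#' @param inner,outer Stimulated annulus, degrees.
#' @return `"45"` or `"135"` (ties broken by a seeded random guess).
#' @export
tilt_decision_cortical <- function(obs, field, frequency,
                                   inner = 0, outer = obs$field_deg) {
  dxu <- as.numeric(field$d_xi) * obs$node_cos -
    as.numeric(field$d_eta) * obs$node_sin
  mask <- obs$node_ecc >= inner & obs$node_ecc <= outer
  if (!any(mask) || !all(is.finite(dxu[mask])))
    return(sample(c("45", "135"), 1))
  f_px <- frequency / obs$ppd
  mag <- function(alpha) {
    Mod(sum(dxu[mask] * exp(-2i * pi * f_px *
                              (cos(alpha) * obs$node_x[mask] +
                                 sin(alpha) * obs$node_y[mask]))))
  }
  m45 <- mag(3 * pi / 4)    # tilt 45: modulation axis at 135 degrees
  m135 <- mag(pi / 4)
  if (m45 == m135) return(sample(c("45", "135"), 1))
  if (m45 > m135) "45" else "135"
}

# Logical mask of grid nodes whose eccentricity falls inside the stimulated
# annulus (degrees), or NULL when the whole field is stimulated.
.stimulus_mask <- function(obs, spec) {
  if (is.null(spec$inner) || is.null(spec$outer)) return(NULL)
  if (spec$inner <= 0 && spec$outer >= obs$field_deg) return(NULL)
  lp <- obs$config$variant %in% c("LP", "LP2S")
  if (lp) {
    ecc <- matrix(obs$mapping$rho0 *
                    obs$mapping$a^(seq_len(obs$nu) - 0.5) / obs$ppd,
                  obs$nu, obs$nv)
  } else {
    ds <- obs$ds
    xs <- (seq_len(obs$nv) - (obs$nv + 1) / 2) * ds / obs$ppd
    ys <- (seq_len(obs$nu) - (obs$nu + 1) / 2) * ds / obs$ppd
    ecc <- sqrt(outer(ys^2, xs^2, `+`))
  }
  (ecc >= spec$inner & ecc <= spec$outer) + 0
}

# Half-resolution sibling observer used by the two-scale variants: same
# filters, grid halved. Cached on the observer's config identity.
.rescale_observer <- function(obs) {
  key <- paste("half", obs$nu, obs$nv, obs$config$sigma, obs$config$fs,
               sep = "_")
  if (!is.null(.op_cache[[key]])) return(.op_cache[[key]])
  o2 <- obs
  o2$nu <- obs$nu %/% 2
  o2$nv <- obs$nv %/% 2
  pr <- o2$nu + 2 * obs$hw
  pc <- if (obs$mirror_cols) o2$nv + 2 * obs$hw else o2$nv
  bank <- gabor_bank(obs$config$N, obs$config$sigma, obs$config$fs,
                     half_width = obs$hw)
  o2$bank_fft <- lapply(bank, .kernel_fft, pr = pr, pc = pc)
  ppr <- o2$nu + 2 * obs$hwp
  ppc <- if (obs$mirror_cols) o2$nv + 2 * obs$hwp else o2$nv
  gx <- seq(-obs$hwp, obs$hwp)
  gk <- exp(-outer(gx^2, gx^2, `+`) / (2 * obs$config$sigma_pool^2))
  o2$pool_fft <- .kernel_fft(gk / sum(gk), ppr, ppc)
  .op_cache[[key]] <- o2
  o2
}
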