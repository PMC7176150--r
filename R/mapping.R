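#' Discrete log-polar retino-cortical mapping
#'
#' Constructs the parameterization of a central blind-spot log-polar grid.
#' The mapping sends a Cartesian point at polar coordinates (rho, theta)
#' to cortical coordinates xi = log_a(rho / rho0), eta = q * theta, where
#' a = (rho_max / rho0)^(1/R) and q = S / (2*pi). Discretizing (xi, eta) to
#' integer (u, v) yields an R x S (rings x sectors) cortical grid. Points
#' with rho < rho0 fall inside the central blind spot and are ignored.
#'
#' Unless given explicitly, the sector count S is set by the isotropy rule:
#' the local circular sampling interval (2*pi/S) * rho0 * a^(u-1) must equal
#' the radial interval rho0 * a^(u-1) * (a - 1) at every ring, which gives
#' S = round(2*pi / (a - 1)) and log-polar pixels with aspect ratio close
#' to 1.
#'
#' Derived quantities stored in the object:
#' * `CR = (Nc * Nr) / (R * S)`, the compression ratio of the Cartesian
#'   image with respect to the cortical one (a proxy for the strength of
#'   cortical magnification);
#' * `Wmax = rho0 * a^R * (1 - 1/a)`, the maximum receptive-field size, i.e.
#'   the width of the outermost ring in Cartesian pixels;
#' * `chi = (1 - log_a(rho0 * (a - 1))) / R`, the fraction of cortical rings
#'   that over-represent the fovea (rings whose radial width is below one
#'   Cartesian pixel).
#'
#' @param Nc,Nr Cartesian image width and height in pixels.
#' @param R Number of cortical rings.
#' @param rho0 Blind-spot radius in Cartesian pixels.
#' @param S Number of sectors; defaults to the isotropy rule.
#' @param rho_max Field radius in Cartesian pixels; defaults to
#'   `0.5 * min(Nc, Nr)`.
#' @return An object of class `lp_mapping`.
#' @examples
#' m <- lp_mapping(128, 128, R = 40, rho0 = 2)
#' m$S       # sector count from the isotropy rule
#' m$CR      # compression ratio
#' @export
lp_mapping <- function(Nc, Nr, R, rho0, S = NULL, rho_max = NULL) {
  if (Nc < 2 || Nr < 2)
    stop("Nc and Nr must be >= 2")
  if (R != round(R) || R < 2)
    stop("R must be an integer >= 2")
  if (is.null(rho_max))
    rho_max <- 0.5 * min(Nc, Nr)
  if (rho0 <= 0 || rho0 >= rho_max)
    stop("invalid geometry: need 0 < rho0 < rho_max")
  a <- (rho_max / rho0)^(1 / R)
  if (is.null(S)) {
    S <- round(2 * pi / (a - 1))
  } else if (S != round(S) || S < 4) {
    stop("S must be an integer >= 4")
  }
  q <- S / (2 * pi)
  m <- list(
    R = as.integer(R), S = as.integer(S),
    rho0 = rho0, rho_max = rho_max,
    a = a, q = q,
    Nc = Nc, Nr = Nr,
    CR = (Nc * Nr) / (R * S),
    Wmax = rho0 * a^R * (1 - 1 / a),
    chi = (1 - log(rho0 * (a - 1), base = a)) / R
  )
  class(m) <- "lp_mapping"
  m
}

#' @export
print.lp_mapping <- function(x, ...) {
  cat(sprintf(
    "log-polar mapping: %d rings x %d sectors, rho0 = %.3g, rho_max = %.4g\n",
    x$R, x$S, x$rho0, x$rho_max))
  cat(sprintf("  a = %.6f, CR = %.3g, Wmax = %.3g px, chi = %.3g\n",
              x$a, x$CR, x$Wmax, x$chi))
  invisible(x)
}

#' Solve the field geometry from a target compression ratio
#'
#' Given the ring count, blind-spot radius and compression ratio on a square
#' image, jointly solves `CR = 4 * rho_max^2 / (R * S)`,
#' `S = 2*pi / (a - 1)` and `a = (rho_max / rho0)^(1/R)` for the field
#' radius `rho_max` by fixed-point iteration, and returns the complete
#' mapping (with the real-valued isotropy S rounded to the nearest integer).
#'
#' @param R Ring count.
#' @param rho0 Blind-spot radius, Cartesian pixels.
#' @param CR Target compression ratio.
#' @param tol Convergence tolerance on rho_max.
#' @return An `lp_mapping`; `Nc = Nr = 2 * rho_max` (real-valued).
#' @export
solve_field_geometry <- function(R, rho0, CR, tol = 1e-10) {
  rho_max <- 50 * rho0
  for (i in 1:500) {
    a <- (rho_max / rho0)^(1 / R)
    S <- 2 * pi / (a - 1)
    new <- sqrt(CR * R * S / 4)
    if (abs(new - rho_max) < tol) break
    rho_max <- new
  }
  lp_mapping(2 * rho_max, 2 * rho_max, R = R, rho0 = rho0,
             rho_max = rho_max)
}

#' Local retino-cortical scale factor
#'
#' The Jacobian of the inverse log-polar mapping is a rotation by the polar
#' angle times the scalar `rho0 * a^xi * ln(a)`: one cortical pixel at
#' cortical eccentricity `xi` covers that many Cartesian pixels. At the
#' foveal edge (`xi = 0`) the scale is `rho0 * ln(a)`; at the peripheral
#' edge (`xi = R`) it is `rho_max * ln(a)`.
#'
#' @param mapping An `lp_mapping`.
#' @param xi Cortical eccentricity (ring coordinate), possibly a vector.
#' @return Scale factor(s) in Cartesian pixels per cortical pixel.
#' @export
cortical_scale <- function(mapping, xi) {
  mapping$rho0 * mapping$a^xi * log(mapping$a)
}

#' Retinal disparity range of a cortical disparity limit
#'
#' Converts a cortical disparity range of +/- `D` cortical pixels into the
#' corresponding retinal range in arcmin at the foveal and peripheral edges
#' of the mapping, for a visual field of radius `field_deg` degrees mapped
#' onto `rho_max` Cartesian pixels.
#'
#' @param mapping An `lp_mapping`.
#' @param D Cortical disparity limit, cortical pixels.
#' @param field_deg Field radius in degrees mapped to `rho_max`.
#' @return Named vector with elements `fovea` and `periphery`, arcmin.
#' @export
disparity_range_arcmin <- function(mapping, D = 1.52, field_deg = 21) {
  arcmin_per_px <- field_deg * 60 / mapping$rho_max
  c(fovea = D * cortical_scale(mapping, 0) * arcmin_per_px,
    periphery = D * cortical_scale(mapping, mapping$R) * arcmin_per_px)
}

#' Receptive-field table of a log-polar grid
#'
#' One row per cortical node (u, v): the Cartesian center, obtained by
#' inverting the mapping at the node midpoint (xi = u + 1/2,
#' eta = v + 1/2), its eccentricity, and the Gaussian receptive-field
#' standard deviation. The RF sigma is half the local radial width of the
#' log-polar pixel, `rho0 * a^u * (a - 1) / 2`, floored at 0.5 Cartesian
#' pixels in the oversampled fovea so that foveal RFs never collapse below
#' the Cartesian pixel grid.
#'
#' @param mapping An `lp_mapping`.
#' @return A data.frame with columns `u`, `v`, `x`, `y`, `ecc`, `sigma`.
#' @export
rf_table <- function(mapping) {
  u <- rep(seq_len(mapping$R) - 1L, times = mapping$S)
  v <- rep(seq_len(mapping$S) - 1L, each = mapping$R)
  rho <- mapping$rho0 * mapping$a^(u + 0.5)
  theta <- (v + 0.5) / mapping$q
  sigma <- pmax(0.5, mapping$rho0 * mapping$a^u * (mapping$a - 1) / 2)
  data.frame(u = u, v = v,
             x = rho * cos(theta), y = rho * sin(theta),
             ecc = rho, sigma = sigma)
}

# Pixel-center coordinates of an Nc x Nr image, origin at the image center.
# Matrix layout: rows index y (Nr of them), columns index x (Nc).
.pixel_grid <- function(Nc, Nr) {
  x <- seq_len(Nc) - (Nc + 1) / 2
  y <- seq_len(Nr) - (Nr + 1) / 2
  list(x = matrix(x, Nr, Nc, byrow = TRUE),
       y = matrix(y, Nr, Nc))
}

#' Sparse forward-transform operator
#'
#' Builds the (R*S) x (Nr*Nc) sparse matrix whose rows hold the normalized
#' Gaussian receptive-field weights of each cortical node over the Cartesian
#' pixels. Weights are truncated at 3 sigma; pixels inside the blind spot
#' (rho < rho0) or beyond rho_max + 3 sigma contribute to no node. Rows are
#' normalized to sum to 1, so the forward transform is a weighted average.
#'
#' The matrix is cached inside the mapping's environment on first use by
#' [to_cortical()]; call this directly only if you need the raw operator.
#'
#' @param mapping An `lp_mapping` with integer `Nc`, `Nr`.
#' @return A `dgCMatrix` of dimension `(R*S) x (Nr*Nc)`.
#' @export
lp_forward_operator <- function(mapping) {
  Nc <- mapping$Nc; Nr <- mapping$Nr
  if (Nc != round(Nc) || Nr != round(Nr))
    stop("forward operator requires integer image dimensions")
  R <- mapping$R; S <- mapping$S
  a <- mapping$a; rho0 <- mapping$rho0
  cx <- (Nc + 1) / 2; cy <- (Nr + 1) / 2
  trip_i <- vector("list", R)
  trip_j <- vector("list", R)
  trip_w <- vector("list", R)
  for (u in seq_len(R) - 1L) {
    sigma <- max(0.5, rho0 * a^u * (a - 1) / 2)
    hw <- ceiling(3 * sigma)
    rho <- rho0 * a^(u + 0.5)
    theta <- (seq_len(S) - 0.5) / mapping$q
    xc <- rho * cos(theta)          # per-sector center, image coords
    yc <- rho * sin(theta)
    off <- seq(-hw, hw)
    nox <- length(off)
    # columns (x offsets) and rows (y offsets) around each center
    jx <- outer(round(xc + cx), off, `+`)   # S x nox candidate columns
    iy <- outer(round(yc + cy), off, `+`)
    keep_s <- seq_len(S)
    idx_i <- idx_j <- wts <- vector("list", S)
    for (s in keep_s) {
      cols <- jx[s, ]; rows <- iy[s, ]
      cols <- cols[cols >= 1 & cols <= Nc]
      rows <- rows[rows >= 1 & rows <= Nr]
      if (!length(cols) || !length(rows)) next
      px <- rep(cols, each = length(rows)) - cx
      py <- rep(rows, times = length(cols)) - cy
      d2 <- (px - xc[s])^2 + (py - yc[s])^2
      w <- exp(-d2 / (2 * sigma^2))
      inside <- d2 <= (3 * sigma)^2 & (px^2 + py^2) >= rho0^2
      if (!any(inside)) next
      lin <- rep(rows, times = length(cols)) +
        (rep(cols, each = length(rows)) - 1L) * Nr
      idx_i[[s]] <- rep.int(u + 1L + (s - 1L) * R, sum(inside))
      idx_j[[s]] <- lin[inside]
      wts[[s]] <- w[inside]
    }
    trip_i[[u + 1L]] <- unlist(idx_i)
    trip_j[[u + 1L]] <- unlist(idx_j)
    trip_w[[u + 1L]] <- unlist(wts)
  }
  W <- Matrix::sparseMatrix(
    i = unlist(trip_i), j = unlist(trip_j), x = unlist(trip_w),
    dims = c(R * S, Nr * Nc))
  rs <- Matrix::rowSums(W)
  rs[rs == 0] <- 1
  Matrix::Diagonal(x = 1 / rs) %*% W
}

.op_cache <- new.env(parent = emptyenv())

.forward_op <- function(mapping) {
  key <- paste(mapping$R, mapping$S, signif(mapping$rho0, 12),
               signif(mapping$rho_max, 12), mapping$Nc, mapping$Nr,
               sep = "_")
  if (is.null(.op_cache[[key]]))
    .op_cache[[key]] <- lp_forward_operator(mapping)
  .op_cache[[key]]
}

#' Forward (retina to cortex) transform
#'
#' Resamples a Cartesian luminance image into the R x S cortical grid; each
#' cortical node takes the Gaussian-weighted average of the Cartesian pixels
#' around its receptive-field center. Pixels inside the blind spot are
#' ignored.
#'
#' @param img Numeric matrix of dimension `Nr x Nc` (rows = y, cols = x).
#' @param mapping An `lp_mapping` matching the image dimensions.
#' @return A `cortical_image`: an R x S matrix (rows = rings u,
#'   cols = sectors v) with the mapping attached as attribute `mapping`.
#' @export
to_cortical <- function(img, mapping) {
  if (!is.matrix(img) || nrow(img) != mapping$Nr || ncol(img) != mapping$Nc)
    stop("image dimensions must match mapping$Nr x mapping$Nc")
  W <- .forward_op(mapping)
  vals <- as.numeric(W %*% as.numeric(img))
  out <- matrix(vals, mapping$R, mapping$S)
  attr(out, "mapping") <- mapping
  class(out) <- c("cortical_image", "matrix")
  out
}

#' Backward (cortex to retina) transform
#'
#' Maps an R x S cortical image back into the Cartesian domain by inverting
#' the log-polar coordinates at every pixel and interpolating bilinearly
#' between cortical nodes, with circular wrap along the sector axis. This
#' inverse is used for visualization and for bringing decoded disparity
#' fields back to retinal coordinates.
#'
#' @param cortical An R x S matrix (a `cortical_image`, or any matrix if
#'   `mapping` is supplied).
#' @param mapping An `lp_mapping`; defaults to the attribute attached by
#'   [to_cortical()].
#' @param fill Value for the blind spot and for pixels beyond `rho_max`;
#'   default is the mean of the cortical image.
#' @return An `Nr x Nc` numeric matrix.
#' @export
to_retinal <- function(cortical, mapping = attr(cortical, "mapping"),
                       fill = NULL) {
  if (is.null(mapping))
    stop("mapping must be supplied or attached to the cortical image")
  if (nrow(cortical) != mapping$R || ncol(cortical) != mapping$S)
    stop("cortical image must be R x S")
  if (is.null(fill)) fill <- mean(cortical)
  bw <- .backward_geom(mapping)
  out <- matrix(fill, mapping$Nr, mapping$Nc)
  out[bw$ok] <- as.numeric(bw$W %*% as.numeric(cortical))
  out
}

# Cached backward-interpolation geometry: for every Cartesian pixel outside
# the blind spot, the bilinear weights over the four surrounding cortical
# nodes (circular wrap in eta), plus the polar geometry reused by the
# disparity back-mapping.
.backward_geom <- function(mapping) {
  key <- paste("bw", mapping$R, mapping$S, signif(mapping$rho0, 12),
               signif(mapping$rho_max, 12), mapping$Nc, mapping$Nr,
               sep = "_")
  if (!is.null(.op_cache[[key]])) return(.op_cache[[key]])
  g <- .pixel_grid(mapping$Nc, mapping$Nr)
  rho <- sqrt(g$x^2 + g$y^2)
  theta <- atan2(g$y, g$x) %% (2 * pi)
  xi <- log(pmax(rho, .Machine$double.xmin) / mapping$rho0) / log(mapping$a)
  ok <- which(rho >= mapping$rho0 & xi <= mapping$R)
  eta <- mapping$q * theta[ok]
  # node (u, v) sits at continuous coordinates (u + 1/2, v + 1/2)
  fu <- pmin(pmax(xi[ok] - 0.5, 0), mapping$R - 1)
  fv <- (eta - 0.5) %% mapping$S
  u0 <- floor(fu); tu <- fu - u0
  v0 <- floor(fv); tv <- fv - v0
  u1 <- pmin(u0 + 1, mapping$R - 1)
  v1 <- (v0 + 1) %% mapping$S
  idx <- function(u, v) u + 1 + v * mapping$R
  n <- length(ok)
  W <- Matrix::sparseMatrix(
    i = rep(seq_len(n), 4),
    j = c(idx(u0, v0), idx(u1, v0), idx(u0, v1), idx(u1, v1)),
    x = c((1 - tu) * (1 - tv), tu * (1 - tv), (1 - tu) * tv, tu * tv),
    dims = c(n, mapping$R * mapping$S))
  geom <- list(ok = ok, W = W,
               rho = rho[ok], theta = theta[ok], xi = fu + 0.5)
  .op_cache[[key]] <- geom
  geom
}
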