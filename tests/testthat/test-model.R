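obs_cache <- new.env()

small_observer <- function(noise = FALSE) {
  key <- if (noise) "noisy" else "clean"
  if (is.null(obs_cache[[key]])) {
    cfg <- if (noise) model_config() else noiseless_config()
    obs_cache[[key]] <- disparity_observer(test_mapping(), cfg)
  }
  obs_cache[[key]]
}

test_that("binocular energy is an exact quadrature sum and phase invariant", {
  expect_equal(complex_energy(3, 4), 25)
  obs <- small_observer()
  set.seed(2)
  # column count matches the noise period so circular shifts are seamless
  tex <- pink_noise(obs$nv, seed = 5)[seq_len(obs$nu), ]
  B <- simple_cells(obs, tex, tex)
  E <- complex_energy(Re(B), Im(B))
  expect_true(all(E >= 0))
  # zero-contrast input gives zero energy
  z <- matrix(0.5, obs$nu, obs$nv)
  Ez <- complex_energy(Re(simple_cells(obs, z, z)),
                       Im(simple_cells(obs, z, z)))
  expect_lt(max(Ez), 1e-12)
  # identical eyes at zero phase difference: response is twice monocular
  k0 <- which(obs$d_set == 0)
  Bm <- simple_cells(obs, tex, z * 0)
  expect_equal(B[, , , k0], 2 * Bm[, , , k0], tolerance = 1e-9)
  # adding a common absolute phase to both eyes leaves energy unchanged
  sh <- shift_columns(tex, 0.61)
  E2 <- complex_energy(Re(simple_cells(obs, sh, sh)),
                       Im(simple_cells(obs, sh, sh)))
  interior <- 10:(obs$nu - 10)
  expect_equal(apply(E[interior, , , ], 3:4, mean),
               apply(E2[interior, , , ], 3:4, mean), tolerance = 0.02)
})

test_that("divisive normalization confers contrast invariance", {
  obs <- small_observer()
  tex <- pink_noise(128, seed = 6)[seq_len(obs$nu), seq_len(obs$nv)]
  B <- simple_cells(obs, tex, tex)
  E <- complex_energy(Re(B), Im(B))
  n1 <- normalize_v1(E, eps = 1e-9)
  # all-equal orientations normalize to 1/N
  Eq <- array(2, c(3, 3, 12, 5))
  expect_equal(normalize_v1(Eq, eps = 0), array(1 / 12, c(3, 3, 12, 5)))
  # scaling the images by 10x changes E by 100x but E_V1 by < 1%
  B10 <- simple_cells(obs, 10 * tex, 10 * tex)
  n10 <- normalize_v1(complex_energy(Re(B10), Im(B10)), eps = 1e-9)
  expect_lt(max(abs(n10 - n1)) / max(n1), 0.01)
  # zero texture stays exactly zero (eps guards 0/0)
  expect_equal(max(normalize_v1(array(0, c(2, 2, 12, 5)))), 0)
})

test_that("population noise respects its amplitude contract", {
  arr <- array(1, c(20, 20, 4, 3))
  set.seed(1)
  noisy <- add_population_noise(arr, 0.3)
  expect_true(all(noisy >= 0))
  expect_true(all(abs(noisy - arr) <= 0.3 + 1e-12))
  expect_identical(add_population_noise(arr, 0), arr)
})

test_that("MT weights and gain behave as specified", {
  # cosine weights: 1 at the matched direction, 0 at 90 degrees away
  expect_equal(cos(0 - 0), 1)
  obs <- small_observer()
  # lambda = 0 collapses MT to exp(0) = 1 before noise
  cfg0 <- noiseless_config(lambda = 0, calibrate_decode = FALSE)
  obs0 <- disparity_observer(test_mapping(), cfg0)
  tex <- pink_noise(128, seed = 7)[seq_len(obs0$nu), seq_len(obs0$nv)]
  B <- simple_cells(obs0, tex, tex)
  Ev1 <- normalize_v1(complex_energy(Re(B), Im(B)))
  Emt <- mt_response(obs0, Ev1)
  expect_equal(range(Emt), c(1, 1), tolerance = 1e-12)
})

test_that("eye swap mirrors the preferred-disparity sign", {
  obs <- small_observer()
  tex <- pink_noise(128, seed = 8)[seq_len(obs$nu), seq_len(obs$nv)]
  sh <- shift_columns(tex, 0.9)
  f_lr <- decode_disparity(obs, mt_response(obs, normalize_v1(
    complex_energy(Re(simple_cells(obs, tex, sh)),
                   Im(simple_cells(obs, tex, sh))))))
  f_rl <- decode_disparity(obs, mt_response(obs, normalize_v1(
    complex_energy(Re(simple_cells(obs, sh, tex)),
                   Im(simple_cells(obs, sh, tex))))))
  expect_equal(stats::median(f_lr$d_eta), -stats::median(f_rl$d_eta),
               tolerance = 0.05)
})

test_that("uniform cortical shifts are recovered within one channel spacing", {
  obs <- small_observer()
  tex <- pink_noise(128, seed = 9)[seq_len(obs$nu), seq_len(obs$nv)]
  spacing <- diff(obs$d_set)[1]
  for (d_true in c(-1.52, -0.7, 0.35, 1.0, 1.52)) {
    fld <- fovdisp:::.stack_one_scale(obs, tex, shift_columns(tex, d_true))
    frac <- mean(abs(fld$d_eta - d_true) <= spacing)
    expect_gte(frac, 0.8)
    expect_equal(stats::median(fld$d_eta), d_true, tolerance = 0.2)
  }
})

test_that("zero-disparity stimuli decode below the noise floor", {
  obs <- small_observer(noise = TRUE)
  tex <- pink_noise(128, seed = 10)[seq_len(obs$nu), seq_len(obs$nv)]
  set.seed(31)
  fld <- fovdisp:::.stack_one_scale(obs, tex, tex)
  spacing <- diff(obs$d_set)[1]
  expect_lt(abs(stats::median(fld$d_eta)), 0.1 * spacing)
  expect_lt(abs(stats::median(fld$d_xi)), 0.1 * spacing)
})

test_that("decoding is linear and an even channel profile decodes to zero", {
  obs <- small_observer()
  Emt <- array(stats::runif(obs$nu * obs$nv * 2 * 5, 0.5, 1.5),
               c(obs$nu, obs$nv, 2, 5))
  f1 <- decode_disparity(obs, Emt, normalize = FALSE)
  f3 <- decode_disparity(obs, 3 * Emt, normalize = FALSE)
  expect_equal(f3$d_xi, 3 * f1$d_xi, tolerance = 1e-12)
  # symmetric profile in d: odd-weighted sum vanishes
  sym <- Emt
  sym[, , , 1] <- sym[, , , 5]; sym[, , , 2] <- sym[, , , 4]
  fs <- decode_disparity(obs, sym, normalize = FALSE)
  expect_lt(max(abs(fs$d_xi)), 1e-10)
  expect_lt(max(abs(fs$d_eta)), 1e-10)
})

test_that("annular pooling is a disjoint partition that sums exactly", {
  obs <- small_observer()
  masks <- region_masks(obs)
  acc <- Reduce(`+`, lapply(masks, `+`, 0))
  expect_true(all(acc <= 1))
  Emt <- array(stats::runif(obs$nu * obs$nv * 2 * 5), c(obs$nu, obs$nv, 2, 5))
  comb <- pool_annuli(Emt, masks)
  full <- array(acc == 1, dim(Emt))
  expect_identical(comb, Emt * full)   # exact, not approximate
  bad <- masks; bad$mid <- masks$fovea
  expect_error(pool_annuli(Emt, bad), "disjoint")
})

test_that("single-region stimuli localize activity to their annulus", {
  obs <- small_observer()
  spec <- stimulus_spec(frequency = 0.18, amplitude = 10, tilt = 45,
                        inner = 3, outer = 9, pixels_per_degree = obs$ppd,
                        size = 192, seed = 3)
  pair <- make_stimulus(spec)
  res <- model_trial(obs, pair)
  masks <- region_masks(obs)
  inside <- mean(abs(res$field$d_xi[masks$mid]))
  outside <- mean(abs(res$field$d_xi[masks$far]))
  expect_gt(inside, 5 * outside)
})

test_that("tilt decisions read the corrugation quadrant", {
  g <- .row_col_grid(96)
  f <- 4 / 96
  map45 <- sin(2 * pi * f * (-g$x + g$y) / sqrt(2))
  map135 <- sin(2 * pi * f * (g$x + g$y) / sqrt(2))
  expect_identical(tilt_decision(map45), "45")
  expect_identical(tilt_decision(map135), "135")
  # known frequency restricts the search band but not the answer
  expect_identical(tilt_decision(map45, frequency = f * 4,
                                 pixels_per_degree = 4), "45")
  # zero maps guess at chance
  set.seed(5)
  guesses <- replicate(400, tilt_decision(matrix(0, 8, 8)))
  expect_gt(mean(guesses == "45"), 0.4)
  expect_lt(mean(guesses == "45"), 0.6)
})

test_that("model variants run and noLP decodes uniformly across the field", {
  m <- test_mapping()
  expect_error(model_config(variant = "bogus"))
  obs_nolp <- disparity_observer(m, noiseless_config(variant = "noLP"))
  pn <- pink_noise(192, seed = 12)
  spec <- stimulus_spec(frequency = 0.1, amplitude = 1, inner = 0,
                        outer = 21, pixels_per_degree = m$rho_max / 21,
                        size = 192)
  d_arcmin <- 6
  pair <- render_stereo(pn, matrix(d_arcmin, 192, 192), spec)
  res <- model_trial(obs_nolp, pair)
  # no eccentricity falloff: same decoded magnitude in center and periphery
  n <- nrow(res$dx)
  ctr <- res$dx[(n / 2 - 5):(n / 2 + 5), (n / 2 - 5):(n / 2 + 5)]
  per <- res$dx[2:8, ]
  expect_equal(stats::median(ctr), stats::median(per), tolerance = 0.35)
  expect_equal(stats::median(ctr), d_arcmin, tolerance = 0.3 * d_arcmin)
  # two-scale variants execute
  obs_2s <- disparity_observer(m, noiseless_config(variant = "LP2S"))
  res2 <- model_trial(obs_2s, pair)
  expect_true(res2$decision %in% c("45", "135"))
})
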