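test_that("staircase applies the three-down one-up rule", {
  st <- staircase_new(start = 20, step1 = 1.5)
  # two correct then one wrong: level increases, counter resets
  st <- staircase_step(st, TRUE)
  st <- staircase_step(st, TRUE)
  expect_equal(st$level, 20)
  st <- staircase_step(st, FALSE)
  expect_equal(st$level, 30)
  expect_equal(st$consecutive_correct, 0L)
  # three consecutive correct: one down step
  st <- staircase_step(st, TRUE)
  st <- staircase_step(st, TRUE)
  st <- staircase_step(st, TRUE)
  expect_equal(st$level, 20)
  # an always-correct observer descends strictly on every third trial
  st2 <- staircase_new(start = 16)
  lv <- numeric(12)
  for (i in 1:12) { lv[i] <- st2$level; st2 <- staircase_step(st2, TRUE) }
  expect_true(all(diff(lv[c(1, 4, 7, 10)]) < 0))
  expect_equal(lv[1:3], rep(16, 3))
})

test_that("staircase reversals are logged and switch the step size", {
  st <- staircase_new(start = 10, step1 = 2, step2 = 1.26, switch_after = 2)
  for (k in 1:2) {
    for (i in 1:3) st <- staircase_step(st, TRUE)
    st <- staircase_step(st, FALSE)
  }
  expect_gte(length(st$reversals), 2)
})

test_that("staircases converge on the 79.4% point of any monotone observer", {
  pf <- function(mu) function(level)
    0.5 + 0.5 * stats::pnorm((log(level) - log(mu)) / 0.4)
  for (i in 1:3) {
    sim <- simulate_staircase(pf(c(2, 5, 0.5)[i]), n_trials = 12000,
                              burn_in = 2000, seed = 100 + i)
    expect_equal(sim$percent_correct, 100 * 0.5^(1 / 3), tolerance = 0.02)
  }
})

test_that("psychometric fit recovers a known threshold within 2%", {
  mu <- log(3); sigma <- 0.5
  set.seed(42)
  levels <- exp(stats::runif(10000, mu - 1.2, mu + 1.2))
  p <- 0.5 + 0.5 * stats::pnorm((log(levels) - mu) / sigma)
  correct <- stats::runif(10000) < p
  fit <- fit_psychometric(levels, correct)
  expect_true(fit$converged)
  expect_equal(fit$threshold75, 3, tolerance = 0.02)
})

test_that("psychometric fit matches a brute-force grid minimizer", {
  set.seed(7)
  levels <- rep(c(1, 2, 4, 8, 16), each = 40)
  p <- 0.5 + 0.5 * stats::pnorm((log(levels) - log(4)) / 0.7)
  correct <- stats::runif(length(levels)) < p
  fit <- fit_psychometric(levels, correct)
  # independent coarse grid search over (mu, sigma) on the same loss
  bins <- sort(unique(log(levels)))
  ph <- vapply(bins, function(b) mean(correct[log(levels) == b]), 0)
  n <- vapply(bins, function(b) sum(log(levels) == b), 0)
  pc <- pmin(pmax(ph, 1 / (2 * n)), 1 - 1 / (2 * n))
  w <- 1 / sqrt(pc * (1 - pc) / n)
  grid <- expand.grid(mu = seq(log(1), log(16), length.out = 220),
                      s = exp(seq(log(0.1), log(3), length.out = 120)))
  loss <- mapply(function(mu, s) {
    pred <- 0.5 + 0.5 * stats::pnorm((bins - mu) / s)
    sum((w * (ph - pred))^2)
  }, grid$mu, grid$s)
  best <- grid[which.min(loss), ]
  expect_equal(fit$mu, best$mu, tolerance = 0.02)
  # the fitted optimum is at least as good as the best grid point
  expect_lte(fit$goodness, min(loss) * 1.001)
})

test_that("degenerate psychophysical data are flagged, not fitted", {
  fit_all <- fit_psychometric(rep(c(2, 4), 20), rep(TRUE, 40))
  expect_false(fit_all$converged)
  expect_equal(fit_all$threshold75, 2)   # pinned at the data bound
  set.seed(8)
  guess <- fit_psychometric(rep(c(1, 2, 4, 8), 100),
                            stats::runif(400) < 0.5)
  expect_false(guess$converged)
})

test_that("log-parabola DSF identities hold and fits are exact on clean data", {
  gmax <- 20; fmax <- 0.3; beta <- 2.5
  expect_equal(dsf_logparabola(fmax, gmax, fmax, beta), log10(gmax))
  # half height at +/- log10(2^beta)/2 in log frequency
  fh <- 10^(log10(fmax) + log10(2^beta) / 2)
  expect_equal(dsf_logparabola(fh, gmax, fmax, beta),
               log10(gmax) - log10(2))
  f <- c(0.04, 0.09, 0.18, 0.35, 0.71, 1.41)
  sens <- 10^dsf_logparabola(f, gmax, fmax, beta)
  fit <- fit_dsf(f, sens)
  expect_equal(fit$gamma_max, gmax, tolerance = 1e-4)
  expect_equal(fit$f_max, fmax, tolerance = 1e-4)
  expect_equal(fit$beta, beta, tolerance = 1e-4)
  # refitting its own predictions returns the same parameters
  fit2 <- fit_dsf(f, 10^fit$fitted)
  expect_equal(fit2$f_max, fit$f_max, tolerance = 1e-8)
  expect_error(fit_dsf(c(0.1, 0.2), c(1, 2)), "at least 3")
})

test_that("MLE combination matches brute force and its exact identities", {
  expect_equal(mle_combine(c(2, 2, 2))$threshold, 2 / sqrt(3))
  expect_equal(mle_combine(c(2, 3, 6))$threshold, sqrt(36 / 14),
               tolerance = 1e-12)
  expect_equal(mle_combine(c(2, 3, 6))$threshold, 1.6036,
               tolerance = 1e-4)
  expect_equal(mle_combine(c(4, Inf, Inf))$threshold, 4)
  set.seed(3)
  for (i in 1:1000) {
    t3 <- stats::runif(3, 0.01, 100)
    expect_equal(mle_combine(t3)$threshold,
                 1 / sqrt(sum(1 / t3^2)), tolerance = 1e-12)
  }
  # optimality and scale equivariance
  set.seed(4)
  for (i in 1:50) {
    t3 <- stats::runif(3, 0.1, 10)
    expect_lte(mle_combine(t3)$threshold, min(t3))
    expect_equal(mle_combine(5 * t3)$threshold,
                 5 * mle_combine(t3)$threshold, tolerance = 1e-12)
  }
  expect_error(mle_combine(c(1, -2, 3)), "positive")
})

test_that("agreement metrics: identity gives r = 1 and clones collapse the ceiling", {
  conds <- paste0("c", 1:12)
  base <- 10 + sin(seq_len(12))
  human <- do.call(rbind, lapply(1:4, function(o)
    data.frame(observer = o, condition = conds, sensitivity = base)))
  model <- data.frame(condition = conds, sensitivity = base)
  am <- agreement_metrics(model, human)
  expect_equal(am$r, 1)
  expect_equal(am$r_squared, 1)
  expect_equal(am$noise_ceiling, c(1, 1))
})

test_that("noise ceiling brackets the analytic attenuation of a noisy cohort", {
  # cohort = common signal + iid noise; the expected leave-one-out r is
  # r = 1 / sqrt((1 + v/s2) * (1 + v/(s2*(n-1)))) with signal variance s2
  set.seed(9)
  conds <- paste0("c", 1:40)
  n_obs <- 8
  signal <- stats::rnorm(40, sd = 1)
  v <- 0.25^2
  human <- do.call(rbind, lapply(1:n_obs, function(o)
    data.frame(observer = o, condition = conds,
               sensitivity = 10 + signal + stats::rnorm(40, sd = 0.25))))
  model <- data.frame(condition = conds, sensitivity = 10 + signal)
  am <- agreement_metrics(model, human, n_boot = 500, seed = 2)
  s2 <- stats::var(signal)
  r_exp <- 1 / sqrt((1 + v / s2) * (1 + v / (s2 * (n_obs - 1))))
  expect_gte(r_exp^2, am$noise_ceiling[1] - 0.05)
  expect_lte(r_exp^2, am$noise_ceiling[2] + 0.05)
  expect_error(agreement_metrics(model, human[human$condition != "c1", ]),
               "grids differ")
})
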