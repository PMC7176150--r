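#' Initialize a three-down one-up staircase
#'
#' Adaptive 2AFC staircase converging on the level producing
#' `(1/2)^(1/3) = 79.4%` correct: the level is divided by the step factor
#' after three consecutive correct responses and multiplied by it after any
#' error. Steps are multiplicative and symmetric (equal up and down log
#' steps, which is what places the convergence point at 79.4%); the step
#' factor shrinks from `step1` to `step2` after `switch_after` reversals.
#'
#' @param start Starting level (peak-to-trough disparity, arcmin); the
#'   default 20 arcmin is clearly visible.
#' @param step1,step2 Multiplicative step factors before/after the switch.
#' @param switch_after Number of reversals before switching to `step2`.
#' @param min_level,max_level Clamps on the level.
#' @return A list of class `staircase` with fields `level`,
#'   `consecutive_correct`, `reversals`, `history`.
#' @export
staircase_new <- function(start = 20, step1 = 1.5, step2 = 1.26,
                          switch_after = 2, min_level = 1e-4,
                          max_level = 120) {
  stopifnot(start > 0, step1 > 1, step2 > 1)
  structure(list(level = start, consecutive_correct = 0L,
                 reversals = numeric(0), history = list(),
                 step1 = step1, step2 = step2,
                 switch_after = as.integer(switch_after),
                 min_level = min_level, max_level = max_level,
                 last_direction = 0L),
            class = "staircase")
}

#' Advance a staircase by one trial
#'
#' @param state A `staircase` from [staircase_new()].
#' @param correct Logical: was the response correct?
#' @return The updated state; `state$level` is the level for the next
#'   trial, and `state$history` logs `(level, correct)` of the trial just
#'   scored.
#' @export
staircase_step <- function(state, correct) {
  state$history[[length(state$history) + 1L]] <-
    list(level = state$level, correct = isTRUE(correct))
  step <- if (length(state$reversals) < state$switch_after)
    state$step1 else state$step2
  direction <- 0L
  if (isTRUE(correct)) {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct >= 3L) {
      state$consecutive_correct <- 0L
      state$level <- max(state$min_level, state$level / step)
      direction <- -1L
    }
  } else {
    state$consecutive_correct <- 0L
    state$level <- min(state$max_level, state$level * step)
    direction <- 1L
  }
  if (direction != 0L) {
    if (state$last_direction != 0L && direction != state$last_direction)
      state$reversals <- c(state$reversals, state$level)
    state$last_direction <- direction
  }
  state
}

#' Simulate a stationary observer driven by a staircase
#'
#' Runs the three-down one-up rule against an observer whose probability
#' of a correct response is a fixed function of the level, and reports the
#' proportion correct over the post-burn-in trials, which for a monotone
#' psychometric function converges to `(1/2)^(1/3)`, about 79.4%.
#'
#' @param pfun Function level -> P(correct), e.g. a cumulative normal in
#'   log level with a 0.5 lower asymptote.
#' @param n_trials Total trials.
#' @param burn_in Trials discarded before scoring.
#' @param seed Optional seed.
#' @param ... Passed to [staircase_new()].
#' @return List with `percent_correct` (post burn-in), `levels` visited,
#'   and the final `state`.
#' @export
simulate_staircase <- function(pfun, n_trials = 12000, burn_in = 1000,
                               seed = NULL, ...) {
  run <- function() {
    st <- staircase_new(...)
    correct <- logical(n_trials)
    levels <- numeric(n_trials)
    for (i in seq_len(n_trials)) {
      levels[i] <- st$level
      correct[i] <- stats::runif(1) < pfun(st$level)
      st <- staircase_step(st, correct[i])
    }
    keep <- seq.int(burn_in + 1L, n_trials)
    list(percent_correct = 100 * mean(correct[keep]),
         levels = levels, state = st)
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}

#' Fit a cumulative-normal psychometric function
#'
#' 2AFC model `p(L) = 0.5 + 0.5 * Phi((log L - mu) / sigma)` fitted to
#' binned proportions by weighted least squares, with weights equal to the
#' reciprocal binomial standard deviation of each bin. The 75% correct
#' point is `exp(mu)`.
#'
#' @param levels Trial levels (> 0).
#' @param correct Logical vector of trial outcomes.
#' @return List of class `psychometric_fit` with `mu`, `sigma`,
#'   `threshold75`, `goodness` (weighted residual sum of squares) and
#'   `converged`. Degenerate data (a single level represented, or all
#'   trials correct / all wrong) give `converged = FALSE` with the
#'   threshold pinned at the corresponding data bound.
#' @export
fit_psychometric <- function(levels, correct) {
  stopifnot(length(levels) == length(correct), all(levels > 0))
  lv <- log(levels)
  bins <- sort(unique(lv))
  p <- vapply(bins, function(b) mean(correct[lv == b]), 0)
  n <- vapply(bins, function(b) sum(lv == b), 0)
  out <- list(mu = NA_real_, sigma = NA_real_, threshold75 = NA_real_,
              goodness = NA_real_, converged = FALSE)
  class(out) <- "psychometric_fit"
  if (length(bins) < 2 || all(correct) || !any(correct)) {
    out$threshold75 <- if (all(correct)) min(levels) else max(levels)
    return(out)
  }
  pc <- pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))
  w <- 1 / sqrt(pc * (1 - pc) / n)      # 1 / binomial SD
  loss <- function(par) {
    pred <- 0.5 + 0.5 * stats::pnorm((bins - par[1]) / exp(par[2]))
    sum((w * (p - pred))^2)
  }
  spread <- max(stats::sd(bins), 0.1)
  starts <- expand.grid(mu = stats::quantile(bins, c(0.25, 0.5, 0.75)),
                        ls = log(spread * c(0.5, 1, 2)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(as.numeric(starts[i, ]), loss,
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  out$mu <- best$par[1]
  out$sigma <- exp(best$par[2])
  out$threshold75 <- exp(best$par[1])
  out$goodness <- best$value
  # guard: the 75% point must be bracketed by data, not extrapolated wildly
  out$converged <- best$convergence == 0 &&
    out$mu < max(bins) + 2 * spread && out$mu > min(bins) - 2 * spread
  out
}

#' Log-parabola disparity sensitivity function
#'
#' `DSF(f) = log10(gamma_max) - log10(2) * ((log10(f) - log10(f_max)) /
#' (log10(2^beta) / 2))^2`: a downward parabola in log-log coordinates with
#' peak gain `gamma_max` at peak frequency `f_max` and full width `beta`
#' octaves at half height (sensitivity falls to `gamma_max / 2` at
#' `log10(f) = log10(f_max) +/- log10(2^beta) / 2`).
#'
#' @param f Spatial frequency, cycles/degree.
#' @param gamma_max Peak gain (1/threshold units).
#' @param f_max Peak frequency, cycles/degree.
#' @param beta Bandwidth at half height, octaves.
#' @return `log10` sensitivity at `f`.
#' @export
dsf_logparabola <- function(f, gamma_max, f_max, beta) {
  log10(gamma_max) - log10(2) *
    ((log10(f) - log10(f_max)) / (log10(2^beta) / 2))^2
}

#' Fit the log-parabola DSF to sensitivity data
#'
#' The log parabola is a quadratic in `log10(f)`, so the least-squares fit
#' of `log10(sensitivity)` reduces to a quadratic regression; the vertex
#' and curvature give `(gamma_max, f_max, beta)` exactly. If the fitted
#' curvature is not negative (no interior peak), a bounded grid search over
#' `f_max` with the remaining parameters profiled out is used instead.
#'
#' @param frequencies Spatial frequencies, cycles/degree (>= 3 values).
#' @param sensitivities Corresponding sensitivities (1/threshold, > 0).
#' @return List of class `dsf_fit` with `gamma_max`, `f_max`, `beta`,
#'   `rss` (residual sum of squares in log10 units) and `fitted`.
#' @export
fit_dsf <- function(frequencies, sensitivities) {
  if (length(frequencies) < 3)
    stop("need at least 3 (frequency, sensitivity) pairs")
  stopifnot(all(frequencies > 0), all(sensitivities > 0),
            length(frequencies) == length(sensitivities))
  x <- log10(frequencies)
  y <- log10(sensitivities)
  co <- unname(stats::coef(stats::lm(y ~ x + I(x^2))))
  if (is.finite(co[3]) && co[3] < 0) {
    x0 <- -co[2] / (2 * co[3])
    g0 <- co[1] - co[2]^2 / (4 * co[3])
    halfw <- sqrt(-log10(2) / co[3])      # log10(2^beta)/2
  } else {
    grid <- seq(min(x) - 1, max(x) + 1, length.out = 200)
    best <- Inf; x0 <- mean(x); g0 <- max(y); halfw <- 1
    for (xm in grid) {
      z <- (x - xm)^2
      cf <- unname(stats::coef(stats::lm(y ~ z)))
      if (!is.finite(cf[2]) || cf[2] >= 0) next
      rss <- sum((y - cf[1] - cf[2] * z)^2)
      if (rss < best) {
        best <- rss; x0 <- xm; g0 <- cf[1]
        halfw <- sqrt(-log10(2) / cf[2])
      }
    }
  }
  beta <- 2 * halfw / log10(2)
  fit <- list(gamma_max = 10^g0, f_max = 10^x0, beta = beta)
  fit$fitted <- dsf_logparabola(frequencies, fit$gamma_max, fit$f_max, beta)
  fit$rss <- sum((y - fit$fitted)^2)
  class(fit) <- "dsf_fit"
  fit
}

#' Maximum-likelihood combination of regional thresholds
#'
#' Assuming independent Gaussian noise per visual-field region and a flat
#' prior, the optimal full-field threshold satisfies
#' `1 / T_opt^2 = sum_v 1 / T_v^2`: the optimal combination is never worse
#' than the best region, and infinite thresholds (unmeasurable regions)
#' simply contribute nothing.
#'
#' @param thresholds Numeric vector of regional thresholds (> 0; `Inf`
#'   allowed).
#' @return List with `threshold` (`T_opt`) and `sensitivity` (`1 / T_opt`).
#' @export
mle_combine <- function(thresholds) {
  if (any(is.na(thresholds)) || any(thresholds <= 0))
    stop("thresholds must be positive (Inf allowed)")
  s2 <- sum(1 / thresholds^2)
  t_opt <- 1 / sqrt(s2)
  list(threshold = t_opt, sensitivity = 1 / t_opt)
}

#' Agreement between model and human sensitivity tables
#'
#' Pearson correlation between the model's sensitivities and the
#' participant-mean sensitivities over a matched condition grid, plus a
#' noise ceiling: each participant is correlated with the mean of the
#' others, the correlations are averaged through Fisher's z transform, a
#' bootstrap over participants gives a 95% interval of that mean, and
#' squaring yields the ceiling on attainable r-squared.
#'
#' @param model Data frame with columns `condition` and `sensitivity`.
#' @param human Data frame with columns `observer`, `condition`,
#'   `sensitivity`; at least two observers for the ceiling.
#' @param n_boot Bootstrap resamples.
#' @param seed Seed for the bootstrap.
#' @return List with `r`, `r_squared`, `noise_ceiling` (length-2 interval
#'   of r-squared values).
#' @export
agreement_metrics <- function(model, human, n_boot = 1000, seed = 1L) {
  conds <- sort(unique(model$condition))
  if (!setequal(conds, unique(human$condition)))
    stop("model and human condition grids differ")
  obs_ids <- unique(human$observer)
  tab <- sapply(obs_ids, function(o) {
    h <- human[human$observer == o, ]
    h$sensitivity[match(conds, h$condition)]
  })
  if (any(is.na(tab))) stop("human table is not complete over the grid")
  hmean <- rowMeans(tab)
  msens <- model$sensitivity[match(conds, model$condition)]
  r <- stats::cor(msens, hmean)
  fisher_z <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
  loo_r <- function(cols) {
    vapply(seq_along(cols), function(i) {
      others <- rowMeans(tab[, cols[-i], drop = FALSE])
      stats::cor(tab[, cols[i]], others)
    }, 0)
  }
  n_obs <- length(obs_ids)
  ceiling_int <- c(1, 1)
  if (n_obs >= 2) {
    if (max(abs(tab - tab[, 1])) == 0) {
      ceiling_int <- c(1, 1)  # all participants identical
    } else {
      boot_mean_r <- .with_seed(seed, vapply(seq_len(n_boot), function(b) {
        cols <- sample(n_obs, n_obs, replace = TRUE)
        if (length(unique(cols)) < 2) return(NA_real_)
        tanh(mean(fisher_z(loo_r(cols)), na.rm = TRUE))
      }, 0))
      ceiling_int <- stats::quantile(boot_mean_r, c(0.025, 0.975),
                                     na.rm = TRUE, names = FALSE)^2
    }
  }
  list(r = r, r_squared = r^2, noise_ceiling = ceiling_int)
}
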