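#' Configuration of the model-as-observer experiment
#'
#' Describes the psychophysical protocol run on the simulated observer:
#' four visual-field conditions (foveal 0-3 deg, mid 3-9 deg, far 9-21 deg,
#' full 0-21 deg) crossed with six corrugation frequencies, thresholds from
#' three-down one-up staircases whose pooled trials are fitted with a
#' cumulative normal. `scale` shrinks the number of staircases and trials
#' proportionally (the laboratory protocol is 24 staircases of 75 trials,
#' i.e. `scale = 1`); simulations in this package's tests and examples use
#' small scales and a reduced image so a condition takes seconds, not
#' hours.
#'
#' @param size Cartesian image side, pixels.
#' @param rings Ring count of the log-polar mapping.
#' @param rho0 Blind-spot radius, pixels.
#' @param frequencies Corrugation frequencies, cycles/degree.
#' @param regions Named list of `(inner, outer)` eccentricity bands,
#'   degrees.
#' @param field_radius Field radius, degrees.
#' @param n_staircases,trials_per_staircase Protocol at `scale = 1`.
#' @param scale Protocol scale factor.
#' @param start_level Staircase starting level, arcmin.
#' @param model A [model_config()].
#' @param seed Base seed; every condition derives its own stream from it.
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(size = 192, rings = 61, rho0 = 2,
                              frequencies = c(0.04, 0.09, 0.18, 0.35,
                                              0.71, 1.41),
                              regions = list(fovea = c(0, 3),
                                             mid = c(3, 9),
                                             far = c(9, 21),
                                             full = c(0, 21)),
                              field_radius = 21,
                              n_staircases = 24, trials_per_staircase = 75,
                              scale = 1, start_level = 20,
                              model = model_config(), seed = 1L) {
  cfg <- list(size = as.integer(size), rings = as.integer(rings),
              rho0 = rho0, frequencies = frequencies, regions = regions,
              field_radius = field_radius,
              n_staircases = max(1L, round(n_staircases * scale)),
              trials_per_staircase = max(5L, round(trials_per_staircase *
                                                     min(1, 2 * scale))),
              start_level = start_level, model = model, seed = seed)
  class(cfg) <- "experiment_config"
  cfg
}

#' Observer implied by an experiment configuration
#' @param cfg An [experiment_config()].
#' @return A [disparity_observer()].
#' @export
observer_from_config <- function(cfg) {
  mapping <- lp_mapping(cfg$size, cfg$size, R = cfg$rings, rho0 = cfg$rho0)
  disparity_observer(mapping, cfg$model, field_deg = cfg$field_radius)
}

# Deterministic sub-seed, kept within the 32-bit integer range.
.sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 104729) %% 2147483647L)
}

#' Measure one threshold of the simulated observer
#'
#' Runs the staircases for one (region, frequency) condition: each trial
#' draws a fresh pink-noise stereogram at the staircase's current
#' peak-to-trough disparity with a random tilt (45/135), the model reports
#' a tilt, and the pooled trials are fitted with the cumulative normal to
#' read the 75% correct threshold.
#'
#' @param obs A [disparity_observer()].
#' @param cfg An [experiment_config()].
#' @param region Length-2 vector `(inner, outer)` degrees, or the name of
#'   a region in `cfg$regions`.
#' @param frequency Corrugation frequency, cycles/degree.
#' @param seed Condition seed; defaults to a stream derived from
#'   `cfg$seed`, the region and the frequency.
#' @return List with `threshold` (arcmin), the `fit`
#'   (a `psychometric_fit`), and `trials` (data.frame of level, correct).
#' @export
run_condition <- function(obs, cfg, region, frequency, seed = NULL) {
  if (is.character(region)) region <- cfg$regions[[region]]
  if (is.null(seed))
    seed <- .sub_seed(cfg$seed, round(1e3 * frequency) +
                        round(region[2] * 17))
  ppd <- obs$ppd
  .with_seed(seed, {
    levels <- numeric(0)
    correct <- logical(0)
    for (sc in seq_len(cfg$n_staircases)) {
      st <- staircase_new(start = cfg$start_level)
      for (tr in seq_len(cfg$trials_per_staircase)) {
        tilt <- sample(c(45, 135), 1)
        spec <- suppressWarnings(stimulus_spec(
          frequency = frequency, amplitude = st$level, tilt = tilt,
          inner = region[1], outer = region[2],
          field_radius = cfg$field_radius,
          pixels_per_degree = ppd, size = cfg$size,
          seed = sample.int(2^30, 1)))
        pair <- suppressWarnings(make_stimulus(spec))
        res <- model_trial(obs, pair)
        ok <- res$decision == as.character(tilt)
        levels <- c(levels, st$level)
        correct <- c(correct, ok)
        st <- staircase_step(st, ok)
      }
    }
    fit <- fit_psychometric(levels, correct)
    list(threshold = fit$threshold75, fit = fit,
         trials = data.frame(level = levels, correct = correct))
  })
}

#' Run the full model-as-observer experiment
#'
#' All regions crossed with all frequencies; returns the threshold table,
#' sensitivities, a DSF fit per region, and the MLE-optimal combination of
#' the three sub-regions at each frequency together with its DSF fit.
#'
#' @param cfg An [experiment_config()].
#' @param obs Optional pre-built observer (rebuilt from `cfg` otherwise).
#' @param progress Print a line per condition?
#' @return List of class `experiment_results` with elements `table`
#'   (data.frame: region, frequency, threshold, sensitivity), `dsf` (named
#'   list of `dsf_fit`), `mle` (data.frame per frequency), `dsf_optimal`.
#' @export
run_experiment <- function(cfg, obs = NULL, progress = FALSE) {
  if (is.null(obs)) obs <- observer_from_config(cfg)
  rows <- list()
  trials <- list()
  for (rg in names(cfg$regions)) {
    for (f in cfg$frequencies) {
      res <- run_condition(obs, cfg, rg, f)
      rows[[length(rows) + 1L]] <- data.frame(
        region = rg, frequency = f, threshold = res$threshold,
        sensitivity = 1 / res$threshold, converged = res$fit$converged)
      trials[[paste(rg, f, sep = "_")]] <- res$trials
      if (progress)
        message(sprintf("%s %.2f cpd: threshold %.3g arcmin",
                        rg, f, res$threshold))
    }
  }
  tab <- do.call(rbind, rows)
  dsf <- lapply(split(tab, tab$region), function(d) {
    ok <- is.finite(d$sensitivity) & d$sensitivity > 0
    if (sum(ok) >= 3) fit_dsf(d$frequency[ok], d$sensitivity[ok]) else NULL
  })
  mle <- NULL
  dsf_opt <- NULL
  if (all(c("fovea", "mid", "far") %in% tab$region)) {
    mle <- mle_report(tab)
    ok <- is.finite(mle$sensitivity_optimal) & mle$sensitivity_optimal > 0
    if (sum(ok) >= 3)
      dsf_opt <- fit_dsf(mle$frequency[ok], mle$sensitivity_optimal[ok])
  }
  structure(list(table = tab, dsf = dsf, mle = mle, dsf_optimal = dsf_opt,
                 trials = trials, config = cfg),
            class = "experiment_results")
}

#' Bootstrap confidence interval of a condition's sensitivity
#'
#' Resamples the pooled trials of one condition with replacement, refits
#' the psychometric function and returns the percentile interval of
#' `1 / threshold75`.
#'
#' @param trials Data.frame with columns `level`, `correct` (as stored in
#'   `experiment_results$trials`).
#' @param n_boot Number of resamples.
#' @param level Coverage (default 0.95).
#' @param seed Seed for the resampling.
#' @return Length-2 vector: lower and upper sensitivity bounds.
#' @export
bootstrap_sensitivity <- function(trials, n_boot = 200, level = 0.95,
                                  seed = 1L) {
  n <- nrow(trials)
  sens <- .with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    fit <- fit_psychometric(trials$level[idx], trials$correct[idx])
    1 / fit$threshold75
  }, 0))
  alpha <- (1 - level) / 2
  stats::quantile(sens, c(alpha, 1 - alpha), names = FALSE, na.rm = TRUE)
}

#' MLE-optimal combination table
#'
#' For each frequency with all three sub-region thresholds present,
#' computes the optimal full-field threshold
#' `1/T_opt^2 = sum_region 1/T^2` and, when a measured full-field row
#' exists, sets it alongside.
#'
#' @param table Data.frame with columns `region`, `frequency`,
#'   `threshold` (regions `fovea`, `mid`, `far` and optionally `full`).
#' @return Data.frame per frequency: `threshold_optimal`,
#'   `sensitivity_optimal`, `threshold_full`, `sensitivity_full`.
#' @export
mle_report <- function(table) {
  freqs <- sort(unique(table$frequency))
  rows <- lapply(freqs, function(f) {
    d <- table[table$frequency == f, ]
    need <- c("fovea", "mid", "far")
    th <- d$threshold[match(need, d$region)]
    if (any(is.na(th))) {
      warning(sprintf("frequency %.3g: missing region, row skipped", f))
      return(NULL)
    }
    opt <- mle_combine(th)
    full <- d$threshold[match("full", d$region)]
    data.frame(frequency = f,
               threshold_optimal = opt$threshold,
               sensitivity_optimal = opt$sensitivity,
               threshold_full = full,
               sensitivity_full = 1 / full)
  })
  do.call(rbind, rows)
}

#' Parameter and architecture sweeps
#'
#' Re-runs the experiment while varying one axis: `"cr"` (target
#' compression ratio, implemented by adjusting the ring count), `"sigma"`
#' (cortical receptive-field size), `"noise"` (a common multiplier on the
#' V1 and MT noise fractions), or `"variant"` (model architecture names).
#'
#' @param cfg Base [experiment_config()].
#' @param axis One of `"cr"`, `"sigma"`, `"noise"`, `"variant"`.
#' @param values Sweep values.
#' @param progress Print progress lines?
#' @return List of class `sweep_results`: per value, the
#'   `experiment_results`; plus `axis` and `values`.
#' @export
run_sweep <- function(cfg, axis = c("cr", "sigma", "noise", "variant"),
                      values, progress = FALSE) {
  axis <- match.arg(axis)
  runs <- lapply(values, function(v) {
    cfg2 <- cfg
    if (axis == "cr") {
      cfg2$rings <- .rings_for_cr(cfg$size, cfg$rho0, v)
    } else if (axis == "sigma") {
      cfg2$model$sigma <- v
    } else if (axis == "noise") {
      cfg2$model$noise_v1 <- cfg$model$noise_v1 * v
      cfg2$model$noise_mt <- cfg$model$noise_mt * v
    } else {
      cfg2$model$variant <- v
    }
    if (progress) message(sprintf("sweep %s = %s", axis, format(v)))
    run_experiment(cfg2, progress = progress)
  })
  structure(list(axis = axis, values = values, runs = runs),
            class = "sweep_results")
}

# Ring count whose isotropy-rule mapping best matches a target CR.
.rings_for_cr <- function(size, rho0, cr_target) {
  rho_max <- size / 2
  best_r <- 2L; best <- Inf
  for (R in 4:400) {
    a <- (rho_max / rho0)^(1 / R)
    S <- round(2 * pi / (a - 1))
    cr <- size^2 / (R * S)
    if (abs(cr - cr_target) < best) {
      best <- abs(cr - cr_target)
      best_r <- R
    }
  }
  best_r
}

#' Peak-parameter summary of a sweep
#'
#' @param sweep A `sweep_results`.
#' @return Data.frame: one row per (value, region) with the fitted DSF
#'   peak frequency, peak gain and bandwidth.
#' @export
sweep_summary <- function(sweep) {
  rows <- list()
  for (i in seq_along(sweep$values)) {
    dsf <- sweep$runs[[i]]$dsf
    for (rg in names(dsf)) {
      if (is.null(dsf[[rg]])) next
      rows[[length(rows) + 1L]] <- data.frame(
        value = sweep$values[i], region = rg,
        f_max = dsf[[rg]]$f_max, gamma_max = dsf[[rg]]$gamma_max,
        beta = dsf[[rg]]$beta)
    }
  }
  do.call(rbind, rows)
}
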