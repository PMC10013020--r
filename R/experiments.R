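#' Experiment drivers
#'
#' These functions reproduce the simulation experiments at configurable
#' scale and return long-format data frames (one row per parameter
#' combination and realization). Every driver is a pure function of its
#' arguments and the master seed: identical inputs give identical tables.
#' The defaults use a scaled-down profile (fewer realizations and
#' surrogates than the full-scale study, which used 100 of each).
#'
#' `run_sim1_bias()` estimates the MIR on uncoupled pairs drawn from a grid
#' of renewal / HDIG configurations, exposing the (negative) small-sample
#' bias of the estimator.
#'
#' @param configs data frame describing the uncoupled-pair grid with columns
#'   `dist` (`"exponential"`, `"gaussian"`, `"inverse_gaussian"`, `"hdig"`)
#'   and the relevant parameter columns (`rate`, `mean`, `sd`, `shape`);
#'   the default covers representative corners of the full grids.
#' @param realizations independent pairs per configuration.
#' @param n_events events per realization.
#' @param cfg an [estimator_config()]; its seed is ignored in favor of
#'   `seed`.
#' @param seed master seed.
#' @return data frame with one row per (configuration, realization) and the
#'   estimated `mir` (nats/s).
#' @export
run_sim1_bias <- function(configs = sim1_default_grid(), realizations = 20,
                          n_events = 300, cfg = estimator_config(),
                          seed = 1) {
  rows <- list()
  for (ci in seq_len(nrow(configs))) {
    cc <- configs[ci, ]
    for (r in seq_len(realizations)) {
      s <- derive_seed(seed, ci * 1000L + r)
      pair <- sim1_pair(cc, n_events, s)
      est <- mir(pair$x, pair$y,
                 estimator_config(k = cfg$k, l = cfg$l, n_u = cfg$n_u,
                                  seed = derive_seed(s, 7L)))
      rows[[length(rows) + 1L]] <-
        data.frame(scenario = "sim1_bias", config = sim1_label(cc),
                   dist = cc$dist, realization = r, mir = est$mir)
    }
  }
  do.call(rbind, rows)
}

#' @rdname run_sim1_bias
#' @export
sim1_default_grid <- function() {
  data.frame(
    dist = c("exponential", "exponential", "gaussian", "gaussian",
             "inverse_gaussian", "inverse_gaussian", "hdig"),
    rate = c(1, 5, NA, NA, NA, NA, NA),
    mean = c(NA, NA, 1, 1, 1, 1, 1),
    sd = c(NA, NA, 0.2, 1.0, NA, NA, NA),
    shape = c(NA, NA, NA, NA, 500, 900, 600))
}

sim1_label <- function(cc) {
  switch(cc$dist,
         exponential = sprintf("poisson rate=%g", cc$rate),
         gaussian = sprintf("gaussian mean=%g sd=%g", cc$mean, cc$sd),
         inverse_gaussian = sprintf("ig mean=%g shape=%g", cc$mean, cc$shape),
         hdig = sprintf("hdig theta0=%g shape=%g", cc$mean, cc$shape))
}

sim1_pair <- function(cc, n_events, seed) {
  gen <- function(s, lab) {
    if (cc$dist == "hdig") {
      simulate_hdig(hdig_params(theta0 = cc$mean, lambda_shape = cc$shape),
                    n_events, seed = s, label = lab)
    } else {
      simulate_renewal(n_events, dist = cc$dist, rate = cc$rate,
                       mean = cc$mean, sd = cc$sd, ig_mean = cc$mean,
                       shape = cc$shape, seed = s, label = lab)
    }
  }
  # both series start at 0: displace the colliding event of y
  resolve_simultaneous(gen(derive_seed(seed, 1L), "X"),
                       gen(derive_seed(seed, 2L), "Y"),
                       jitter = TRUE, seed = derive_seed(seed, 3L))
}

#' Coupled-simulation coupling curves
#'
#' `run_sim2_curve()` sweeps the delay-variability parameter `sigma_pat` and
#' the embedding length `l` over realizations of the heartbeat /
#' pulse-arrival simulation, recording MIR, cMIR and the surrogate
#' significance verdict for each realization. `run_sim3_curve()` does the
#' same for the common-driver simulation, where `sigma_pat` acts as a
#' coupling (rather than de-coupling) parameter.
#'
#' @param sigma_grid delay standard deviations to test (s).
#' @param l_grid embedding lengths to test.
#' @param realizations realizations per grid point.
#' @param n_events events per realization.
#' @param M surrogates per realization.
#' @param method surrogate engine.
#' @param k neighbor count.
#' @param seed master seed.
#' @return data frame with columns `scenario`, `sigma_pat`, `l`,
#'   `realization`, `mir`, `cmir`, `significant`.
#' @export
run_sim2_curve <- function(sigma_grid = c(0.010, 0.110, 0.235),
                           l_grid = 1, realizations = 20, n_events = 300,
                           M = 20, method = "local_permutation", k = 30,
                           seed = 1) {
  curve_driver("sim2_curve", sigma_grid, l_grid, realizations, n_events, M,
               method, k, seed, sim2_pair)
}

#' @rdname run_sim2_curve
#' @export
run_sim3_curve <- function(sigma_grid = c(0.010, 0.110, 0.235),
                           l_grid = 1, realizations = 20, n_events = 300,
                           M = 20, method = "local_permutation", k = 30,
                           seed = 1) {
  curve_driver("sim3_curve", sigma_grid, l_grid, realizations, n_events, M,
               method, k, seed,
               function(sigma, n, s) simulate_common_driver(sigma, n, seed = s))
}

sim2_pair <- function(sigma, n_events, seed) {
  x <- simulate_hdig(hdig_params(), n_events, seed = derive_seed(seed, 1L))
  y <- simulate_pat_process(x, pat_params(sigma), seed = derive_seed(seed, 2L))
  list(x = x, y = y)
}

curve_driver <- function(scenario, sigma_grid, l_grid, realizations, n_events,
                         M, method, k, seed, pair_fun) {
  rows <- list()
  for (si in seq_along(sigma_grid)) {
    for (r in seq_len(realizations)) {
      s <- derive_seed(seed, si * 10000L + r)
      pair <- pair_fun(sigma_grid[si], n_events, s)
      for (l in l_grid) {
        est <- cmir(pair$x, pair$y,
                    estimator_config(k = k, l = l, seed = derive_seed(s, l)),
                    surrogate_config(method = method, M = M,
                                     seed = derive_seed(s, 100L + l)))
        rows[[length(rows) + 1L]] <-
          data.frame(scenario = scenario, sigma_pat = sigma_grid[si], l = l,
                     realization = r, mir = est$mir$mir, cmir = est$cmir,
                     significant = est$significant)
      }
    }
  }
  do.call(rbind, rows)
}

#' Sample-size dependence of the MIR estimate
#'
#' Runs the coupled heartbeat / pulse-arrival simulation at a fixed
#' `sigma_pat` for several series lengths, recording MIR and cMIR. Larger
#' samples shrink both the negative bias and the variance of the estimates.
#'
#' @param n_grid series lengths (events).
#' @param sigma_pat delay standard deviation (s).
#' @param realizations realizations per length.
#' @param M surrogates per realization (cMIR); `M = 0` skips the correction.
#' @param method surrogate engine.
#' @param k neighbor count.
#' @param l embedding length.
#' @param seed master seed.
#' @return data frame with columns `scenario`, `n_events`, `realization`,
#'   `mir`, `cmir`.
#' @export
run_samplesize_sweep <- function(n_grid = c(300, 5000), sigma_pat = 0.235,
                                 realizations = 10, M = 10,
                                 method = "local_permutation", k = 30, l = 1,
                                 seed = 1) {
  rows <- list()
  for (ni in seq_along(n_grid)) {
    for (r in seq_len(realizations)) {
      s <- derive_seed(seed, ni * 10000L + r)
      pair <- sim2_pair(sigma_pat, n_grid[ni], s)
      cfg <- estimator_config(k = k, l = l, seed = derive_seed(s, 7L))
      if (M >= 2) {
        est <- cmir(pair$x, pair$y, cfg,
                    surrogate_config(M = M, method = method,
                                     seed = derive_seed(s, 8L)))
        m_val <- est$mir$mir
        c_val <- est$cmir
      } else {
        m_val <- mir(pair$x, pair$y, cfg)$mir
        c_val <- NA_real_
      }
      rows[[length(rows) + 1L]] <-
        data.frame(scenario = "samplesize_sweep", n_events = n_grid[ni],
                   sigma_pat = sigma_pat, realization = r, mir = m_val,
                   cmir = c_val)
    }
  }
  do.call(rbind, rows)
}

#' Per-subject analysis of heartbeat and systolic event files
#'
#' Implements the per-record workflow for real data: from the series of R
#' times and systolic times it derives the RR intervals (differences of
#' consecutive R times) and the PAT intervals (each systolic time minus the
#' preceding R time), reports their means and standard deviations, and
#' estimates the cMIR between the two event series for each requested
#' embedding length. Systolic events with no preceding R event are excluded
#' with a warning; simultaneous events follow the package's default policy
#' (error unless jittered beforehand).
#'
#' @param r_times heartbeat `event_series` or path to an event file.
#' @param systolic_times systolic `event_series` or path to an event file.
#' @param l_grid embedding lengths for the cMIR sweep; `integer(0)` skips the
#'   estimation and reports interval statistics only.
#' @param k neighbor count.
#' @param M surrogates per estimate.
#' @param method surrogate engine.
#' @param seed master seed.
#' @return a list (JSON-serializable via [jsonlite::toJSON()]) with interval
#'   statistics (`rr`, `pat`: mean and sd in seconds), a `cmir` table (one
#'   entry per `l` with mir, cmir, surrogate median, 95th percentile and
#'   significance), and the echoed configuration.
#' @export
analyze_pair <- function(r_times, systolic_times, l_grid = 1:5, k = 30,
                         M = 100, method = "local_permutation", seed = NULL) {
  x <- if (inherits(r_times, "event_series")) r_times else read_events(r_times)
  y <- if (inherits(systolic_times, "event_series")) systolic_times
       else read_events(systolic_times)
  # pair each systolic event with the preceding R event
  prec <- findInterval(y$times, x$times)
  unpaired <- prec == 0
  if (any(unpaired)) {
    warning(sum(unpaired), " systolic events precede the first R event; excluded")
    y <- event_series(y$times[!unpaired], label = y$label)
    prec <- prec[!unpaired]
  }
  rr <- diff(x$times)
  pat <- y$times - x$times[prec]
  res <- lapply(l_grid, function(l) {
    est <- cmir(x, y,
                estimator_config(k = k, l = l, seed = derive_seed(seed, l)),
                surrogate_config(method = method, M = M,
                                 seed = derive_seed(seed, 100L + l)))
    list(l = l, mir = est$mir$mir, cmir = est$cmir,
         surrogate_median = est$surrogate_median,
         surrogate_p95 = est$percentile95, significant = est$significant)
  })
  list(rr = list(mean = mean(rr), sd = stats::sd(rr), n = length(rr)),
       pat = list(mean = mean(pat), sd = stats::sd(pat), n = length(pat)),
       cmir = res,
       config = list(k = k, norm = "max", n_u = "N_X", M = M,
                     surrogate_method = method, l_grid = l_grid, seed = seed))
}
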