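test_that("TER of independent Poisson processes is near zero at large N", {
  x <- simulate_renewal(10000, "exponential", rate = 1, seed = 1)
  y <- simulate_renewal(10000, "exponential", rate = 1, seed = 2)
  p <- resolve_simultaneous(x, y, jitter = TRUE, seed = 3)
  for (combine in c("shared_radius", "fixed_k")) {
    est <- ter(p$x, p$y, estimator_config(seed = 4, combine = combine))
    expect_lt(abs(est$value), 0.05)
  }
})

test_that("the TER value equals its four-entropy combination exactly", {
  pair <- sim2_fixture(n_events = 250, seed = 12)
  for (combine in c("shared_radius", "fixed_k")) {
    est <- ter(pair$x, pair$y,
               estimator_config(k = 10, l = 2, seed = 5, combine = combine))
    h <- est$entropy_terms
    expect_identical(
      est$value,
      est$rate * (h[["h_pu_joint"]] - h[["h_px_joint"]] +
                  h[["h_px_target"]] - h[["h_pu_target"]]))
  }
})

test_that("fixed-k combination reduces to log distance ratios exactly", {
  # with equal sample sizes and a common k the digamma constants cancel and
  # only the per-sample log ratios of neighbor distances remain
  pair <- sim2_fixture(n_events = 250, seed = 12)
  cfg <- estimator_config(k = 10, l = 2, seed = 5, combine = "fixed_k")
  est <- ter(pair$x, pair$y, cfg, details = TRUE)
  jx <- est$details$joint_x
  ju <- est$details$joint_u
  expect_equal(nrow(jx), nrow(ju))  # N_U = N_X
  l <- cfg$l
  n <- nrow(jx)
  mx <- jx[, seq_len(l), drop = FALSE]
  mu <- ju[, seq_len(l), drop = FALSE]
  eps_jx <- ppmir:::knn_max_dist(jx, jx, cfg$k, TRUE)
  eps_ju <- ppmir:::knn_max_dist(jx, ju, cfg$k, FALSE)
  eps_mx <- ppmir:::knn_max_dist(mx, mx, cfg$k, TRUE)
  eps_mu <- ppmir:::knn_max_dist(mx, mu, cfg$k, FALSE)
  reduced <- est$rate / n *
    sum(2 * l * log(eps_ju / eps_jx) + l * log(eps_mx / eps_mu))
  expect_equal(est$value, reduced, tolerance = 1e-12)
})

test_that("shared-radius combination reduces to digamma counts exactly", {
  pair <- sim2_fixture(n_events = 250, seed = 12)
  cfg <- estimator_config(k = 10, l = 2, seed = 5)
  est <- ter(pair$x, pair$y, cfg, details = TRUE)
  jx <- est$details$joint_x
  ju <- est$details$joint_u
  l <- cfg$l
  mx <- jx[, seq_len(l), drop = FALSE]
  mu <- ju[, seq_len(l), drop = FALSE]
  eps <- ppmir:::knn_max_dist(jx, jx, cfg$k, TRUE)
  n_ju <- ppmir:::range_count_max(jx, ju, eps, FALSE)
  n_mx <- ppmir:::range_count_max(mx, mx, eps, TRUE)
  n_mu <- ppmir:::range_count_max(mx, mu, eps, FALSE)
  reduced <- est$rate * mean(digamma(cfg$k) - digamma(n_ju + 1) -
                             digamma(n_mx + 1) + digamma(n_mu + 1))
  expect_equal(est$value, reduced, tolerance = 1e-12)
})

test_that("time rescaling divides the rate estimate by the scale factor", {
  pair <- sim2_fixture(n_events = 200, seed = 21)
  cfg <- estimator_config(k = 15, seed = 9)
  est <- ter(pair$x, pair$y, cfg)
  for (cc in c(0.5, 3)) {
    scaled <- ter(event_series(pair$x$times * cc),
                  event_series(pair$y$times * cc), cfg)
    expect_equal(scaled$value * cc, est$value, tolerance = 1e-8)
  }
})

test_that("MIR is the exact sum of the two directed rates and is seeded", {
  pair <- sim2_fixture(n_events = 250, seed = 33)
  cfg <- estimator_config(seed = 77)
  m1 <- mir(pair$x, pair$y, cfg)
  expect_identical(m1$mir, m1$ter_xy$value + m1$ter_yx$value)
  m2 <- mir(pair$x, pair$y, cfg)
  expect_identical(m1$mir, m2$mir)
  # the dominant direction is from the heartbeat to the arrival process
  expect_gt(m1$ter_xy$value, 0)
})

test_that("cMIR subtracts the surrogate median and tests the 95th percentile", {
  pair <- sim2_fixture(n_events = 200, seed = 55)
  est <- cmir(pair$x, pair$y, estimator_config(k = 15, seed = 3),
              surrogate_config(method = "shuffle", M = 20, seed = 4))
  expect_length(est$surrogate_values, 20)
  expect_identical(est$cmir, est$mir$mir - median(est$surrogate_values))
  expect_identical(est$percentile95,
                   unname(quantile(est$surrogate_values, 0.95, type = 7)))
  expect_identical(est$significant, est$mir$mir > est$percentile95)
  expect_identical(significance_test(est), est$significant)
  expect_error(cmir(pair$x, pair$y, estimator_config(seed = 1),
                    surrogate_config(M = 1)), "M = 2")
})

test_that("significance verdict follows the surrogate distribution", {
  fake <- structure(list(mir = list(mir = 1.0),
                         surrogate_values = seq(0, 0.5, length.out = 50)),
                    class = "cmir_estimate")
  expect_true(significance_test(fake))       # above every surrogate
  fake$mir$mir <- 0.1                         # below the surrogate median
  expect_false(significance_test(fake))
})

test_that("cMIR reports serialize to JSON with configuration echoed", {
  pair <- sim2_fixture(n_events = 200, seed = 55)
  cfg <- estimator_config(k = 15, seed = 3)
  est <- cmir(pair$x, pair$y, cfg,
              surrogate_config(method = "shuffle", M = 10, seed = 4))
  js <- jsonlite::fromJSON(cmir_report(est, cfg))
  expect_equal(js$mir, est$mir$mir)
  expect_equal(js$cmir, est$cmir)
  expect_equal(js$config$k, 15)
  expect_equal(js$config$norm, "max")
  f <- tempfile(fileext = ".json")
  cmir_report(est, cfg, path = f)
  expect_equal(jsonlite::fromJSON(f)$cmir, est$cmir)
})
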