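test_that("interval shuffling preserves the amplitude multiset exactly", {
  iv <- intervals(sim2_fixture(n_events = 120, seed = 2)$x)
  s <- surrogate_shuffle(iv, seed = 5)
  expect_identical(sort(s$intervals), sort(iv$intervals))
  expect_identical(sum(s$intervals), sum(iv$intervals))
  expect_identical(s$start_time, iv$start_time)
  expect_identical(surrogate_shuffle(iv, seed = 5)$intervals, s$intervals)
  expect_false(identical(surrogate_shuffle(iv, seed = 6)$intervals,
                         s$intervals))
})

test_that("IAAFT preserves amplitudes and approximates the spectrum", {
  iv <- intervals(sim2_fixture(n_events = 300, seed = 4)$x)
  s <- surrogate_iaaft(iv, seed = 11)
  expect_identical(sort(s$intervals), sort(iv$intervals))
  expect_identical(surrogate_iaaft(iv, seed = 11)$intervals, s$intervals)
  s2 <- surrogate_iaaft(iv, seed = 12)
  expect_identical(sort(s2$intervals), sort(iv$intervals))
  expect_false(identical(s2$intervals, s$intervals))

  # periodogram of the IAAFT surrogate is closer to the original's than a
  # plain shuffle's, for an autocorrelated interval series
  pgram <- function(v) spec.pgram(v, taper = 0, plot = FALSE, detrend = TRUE)$spec
  p0 <- pgram(iv$intervals)
  mse_iaaft <- mean((pgram(s$intervals) - p0)^2)
  mse_shuffle <- mean((pgram(surrogate_shuffle(iv, seed = 11)$intervals) - p0)^2)
  expect_lt(mse_iaaft, mse_shuffle)
  expect_error(surrogate_iaaft(interval_series(1:5), seed = 1), "at least 8")
})

test_that("autocorrelation-preserving surrogate matches low-lag acf", {
  iv <- intervals(sim2_fixture(n_events = 300, seed = 6)$x)
  s <- surrogate_jodi(iv, seed = 13)
  expect_identical(sort(s$intervals), sort(iv$intervals))
  expect_identical(surrogate_jodi(iv, seed = 13)$intervals, s$intervals)
  ac <- function(v, lag) cor(v[-(1:lag)], v[seq_len(length(v) - lag)])
  expect_lt(abs(ac(s$intervals, 1) - ac(iv$intervals, 1)), 0.05)
  # but the ordering itself differs from the original
  expect_false(identical(s$intervals, iv$intervals))
})

test_that("local permutation alters only source blocks, preserving multisets", {
  pair <- sim2_fixture(n_events = 200, seed = 8)
  for (l in c(1, 3)) {
    joint <- embed_at_events(pair$x, pair$y, l)$joint
    perm <- local_permutation(joint, seed = 31)
    m0 <- joint$samples
    m1 <- perm$samples
    expect_identical(m1[, seq_len(l), drop = FALSE],
                     m0[, seq_len(l), drop = FALSE])
    src0 <- m0[, l + seq_len(l), drop = FALSE]
    src1 <- m1[, l + seq_len(l), drop = FALSE]
    expect_identical(src1[order(src1[, 1]), , drop = FALSE],
                     src0[order(src0[, 1]), , drop = FALSE])
    # no row keeps its own source block (derangement-style assignment)
    expect_false(any(rowSums(src1 != src0) == 0))
    expect_identical(local_permutation(joint, seed = 31)$samples, m1)
  }
  expect_error(local_permutation(matrix(0, 5, 2), l = 1,
                                 n_perm_neighbors = 10), "n_perm_neighbors")
})

test_that("surrogate MIR values realize the uncoupled null", {
  pair <- sim2_fixture(sigma_pat = 0.010, n_events = 300, seed = 14)
  cfg <- estimator_config(l = 5, seed = 9)
  m0 <- mir(pair$x, pair$y, cfg)$mir
  sv <- surrogate_mir_values(pair$x, pair$y, cfg,
                             surrogate_config(M = 20, seed = 15))
  expect_length(sv, 20)
  # permutation destroys the conditional source-target dependence
  expect_lt(median(sv), m0)
  sv2 <- surrogate_mir_values(pair$x, pair$y, cfg,
                              surrogate_config(M = 20, seed = 15))
  expect_identical(sv, sv2)
})

test_that("local permutation surrogates retain more MIR than shuffling", {
  pair <- sim2_fixture(sigma_pat = 0.010, n_events = 300, seed = 16)
  cfg <- estimator_config(l = 1, seed = 19)
  sv_lp <- surrogate_mir_values(pair$x, pair$y, cfg,
                                surrogate_config(M = 20, seed = 17))
  sv_sh <- surrogate_mir_values(pair$x, pair$y, cfg,
                                surrogate_config(method = "shuffle", M = 20,
                                                 seed = 17))
  expect_gt(median(sv_lp), median(sv_sh))
})

test_that("interval-engine surrogate series preserve count and duration", {
  pair <- poisson_fixture(n_events = 200, seed = 23)
  iv <- intervals(pair$y)
  for (gen in list(surrogate_shuffle, surrogate_iaaft, surrogate_jodi)) {
    ys <- events_from_intervals(gen(iv, seed = 3))
    expect_equal(n_events(ys), n_events(pair$y))
    expect_equal(duration(ys), duration(pair$y))
    expect_identical(ys$times[1], pair$y$times[1])
  }
})
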