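test_that("embeddings at target events follow the interval construction", {
  x <- event_series(c(1.0, 2.0, 3.5, 4.0))
  y <- event_series(c(0.5, 2.6, 3.8))
  emb <- embed_at_events(x, y, l = 2)
  expect_equal(emb$joint$sample_times, c(3.5, 4.0))
  expect_equal(emb$joint$samples[1, ], c(1.5, 1.0, 0.9, 2.1))
  expect_equal(emb$joint$samples[2, ], c(0.5, 1.5, 0.2, 1.2))
  expect_equal(emb$target_only$samples, emb$joint$samples[, 1:2])

  emb1 <- embed_at_events(x, y, l = 1)
  i <- which(emb1$joint$sample_times == 2.0)
  expect_equal(emb1$joint$samples[i, ], c(1.0, 1.5))

  late <- event_series(c(5, 6))  # all source events after the last target
  expect_error(embed_at_events(x, late, l = 1), "full joint history")
})

test_that("embeddings at arbitrary times use time-since-last-event", {
  x <- event_series(c(1.0, 2.0))
  y <- event_series(c(0.5, 1.5))
  emb <- embed_at_times(x, y, l = 2, u_times = 3.0)
  expect_equal(emb$joint$samples[1, ], c(1.0, 1.0, 1.5, 1.0))

  emb1 <- embed_at_times(x, y, l = 1, u_times = 3.0)
  expect_equal(emb1$joint$samples[1, ], c(1.0, 1.5))

  # u coinciding with an event time is rejected; only valid u survive
  emb2 <- embed_at_times(x, y, l = 1, u_times = c(2.0, 1.75))
  expect_equal(emb2$joint$sample_times, 1.75)
  expect_error(embed_at_times(x, y, l = 1, u_times = c(0.2, 1.0)),
               "full joint history")
})

test_that("embedding coordinates respect shift and scale symmetries", {
  pair <- sim2_fixture(n_events = 60, seed = 3)
  for (l in c(1, 3)) {
    ref <- embed_at_events(pair$x, pair$y, l)
    shift <- embed_at_events(
      event_series(pair$x$times + 137.5), event_series(pair$y$times + 137.5), l)
    expect_equal(shift$joint$samples, ref$joint$samples)
    scl <- embed_at_events(
      event_series(pair$x$times * 2.5), event_series(pair$y$times * 2.5), l)
    expect_equal(scl$joint$samples, 2.5 * ref$joint$samples)
    expect_true(all(ref$joint$samples >= 0))
    expect_equal(ncol(ref$joint$samples), 2 * l)
    expect_equal(ncol(ref$target_only$samples), l)
  }
})

test_that("usable-row count matches the construction rule exactly", {
  pair <- sim2_fixture(n_events = 80, seed = 9)
  tx <- pair$x$times
  ty <- pair$y$times
  for (l in 1:3) {
    emb <- embed_at_events(pair$x, pair$y, l)
    p <- findInterval(tx, ty)
    expect_equal(nrow(emb$joint$samples), sum(seq_along(tx) > l & p >= l))
  }
})

test_that("random time sampling is seeded and confined to the valid window", {
  pair <- sim2_fixture(n_events = 100, seed = 5)
  u1 <- sample_random_times(pair$x, pair$y, l = 2, seed = 11)
  u2 <- sample_random_times(pair$x, pair$y, l = 2, seed = 11)
  expect_identical(u1, u2)
  lo <- max(pair$x$times[2], pair$y$times[2])
  hi <- max(max(pair$x$times), max(pair$y$times))
  expect_true(all(u1 > lo & u1 < hi))
  # default draw count equals the number of usable target events
  expect_length(u1, nrow(embed_at_events(pair$x, pair$y, 2)$joint$samples))
  expect_length(sample_random_times(pair$x, pair$y, 1, n_u = 300, seed = 1), 300)
  # every drawn time yields a full embedding row
  expect_equal(nrow(embed_at_times(pair$x, pair$y, 2, u1)$joint$samples),
               length(u1))
})
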