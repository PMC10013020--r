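band_peak <- function(v, lo, hi) {
  # frequency (cycles/interval) of the smoothed periodogram peak inside a band
  sp <- spec.pgram(v, spans = c(11, 11), taper = 0, detrend = TRUE,
                   plot = FALSE)
  inside <- sp$freq >= lo & sp$freq <= hi
  sp$freq[inside][which.max(sp$spec[inside])]
}

test_that("pole specifications convert to AR coefficients and back", {
  a <- ar_coeffs_from_poles(list(c(0.8, 2 * pi * 0.1)))
  expect_equal(a, c(2 * 0.8 * cos(2 * pi * 0.1), -0.64), tolerance = 1e-12)
  expect_equal(ar_coeffs_from_poles(list(0.6)), 0.6)
  five <- ar_coeffs_from_poles(list(c(0.8, 2 * pi * 0.1),
                                    c(0.92, 2 * pi * 0.25), 0.6))
  expect_length(five, 5)
  mods <- sort(Mod(polyroot(c(-rev(five), 1))))
  expect_equal(mods, sort(c(0.8, 0.8, 0.92, 0.92, 0.6)), tolerance = 1e-10)
  expect_error(ar_coeffs_from_poles(list(1.01)), "modulus")
})

test_that("renewal simulators reproduce their interval distributions", {
  x <- simulate_renewal(10000, "exponential", rate = 5, seed = 1)
  w <- diff(x$times)
  expect_lt(abs(mean(w) - 0.2), 2 * sd(w) / sqrt(length(w)))
  expect_equal(n_events(x), 10000)
  expect_true(all(w > 0))

  ig <- simulate_renewal(10000, "inverse_gaussian", ig_mean = 1, shape = 600,
                         seed = 2)
  expect_equal(sd(diff(ig$times)), sqrt(1 / 600), tolerance = 0.05)

  g <- simulate_renewal(5000, "gaussian", mean = 0.8, sd = 1.0, seed = 3)
  expect_true(all(diff(g$times) > 0))
  expect_gt(attr(g, "truncation_frac"), 0.1)  # heavy truncation at mu < sigma
})

test_that("Poisson counts have unit Fano factor on long runs", {
  x <- simulate_renewal(20000, "exponential", rate = 1, seed = 4)
  counts <- table(cut(x$times, seq(0, floor(duration(x)), by = 10)))
  expect_equal(var(as.numeric(counts)) / mean(counts), 1, tolerance = 0.15)
})

test_that("heartbeat model produces oscillations in the expected bands", {
  x <- simulate_hdig(hdig_params(), 10000, seed = 5)
  w <- diff(x$times)
  expect_true(all(w > 0))
  expect_equal(mean(w), 1, tolerance = 0.05)
  expect_gt(band_peak(w, 0.04, 0.15), 0.08)   # low-frequency peak ~0.1
  expect_lt(band_peak(w, 0.04, 0.15), 0.12)
  expect_gt(band_peak(w, 0.15, 0.4), 0.2)     # high-frequency peak ~0.25
  expect_lt(band_peak(w, 0.15, 0.4), 0.3)
  # degenerate AR reduces to a renewal inverse-Gaussian process
  r <- simulate_hdig(hdig_params(theta = numeric(0)), 5000, seed = 6)
  expect_equal(mean(diff(r$times)), 1, tolerance = 0.01)
  expect_identical(simulate_hdig(hdig_params(), 300, seed = 7)$times,
                   simulate_hdig(hdig_params(), 300, seed = 7)$times)
})

test_that("innovation calibration hits the requested delay variability", {
  expect_identical(calibrate_innovation_sd(0, 0, 0.1), 0.1)
  a <- ar_coeffs_from_poles(list(c(0.8, 2 * pi * 0.1)))
  s_u <- calibrate_innovation_sd(a[1], a[2], 0.085)
  expect_equal(s_u, 0.085 / 2.119, tolerance = 0.001)
  tau <- ppmir:::ar2_deviations(1e5, a[1], a[2], s_u)
  expect_lt(abs(sd(tau) - 0.085) / 0.085, 0.02)
  expect_error(calibrate_innovation_sd(1.5, 0.5, 0.1), "stationary")
})

test_that("pulse arrival process matches mean delay and variability", {
  x <- simulate_hdig(hdig_params(), 10000, seed = 8)
  y <- simulate_pat_process(x, pat_params(0.085), seed = 9)
  tau <- y$times - x$times
  expect_lt(abs(mean(tau) - 0.3) / 0.3, 0.02)
  expect_lt(abs(sd(tau) - 0.085) / 0.085, 0.05)
  expect_gt(band_peak(tau, 0.04, 0.15), 0.08)
  expect_lt(band_peak(tau, 0.04, 0.15), 0.12)
  # strict interleaving when delays are small relative to the intervals
  y2 <- simulate_pat_process(x, pat_params(0.010), seed = 10)
  expect_true(all(y2$times > x$times))
  expect_equal(findInterval(y2$times, x$times), seq_len(n_events(x)))
})

test_that("common-driver scenario injects shared low-frequency power", {
  lf_power <- function(sig) {
    p <- simulate_common_driver(sig, 3000, seed = 11)
    w <- diff(p$x$times)
    sp <- spec.pgram(w, spans = c(11, 11), taper = 0, detrend = TRUE,
                     plot = FALSE)
    mean(sp$spec[sp$freq >= 0.04 & sp$freq <= 0.15])
  }
  pw <- c(lf_power(0.010), lf_power(0.110), lf_power(0.235))
  expect_true(all(diff(pw) > 0))
  p <- simulate_common_driver(0.05, 500, seed = 12)
  expect_true(all(p$y$times > p$x$times))
  expect_identical(simulate_common_driver(0.1, 200, seed = 13)$x$times,
                   simulate_common_driver(0.1, 200, seed = 13)$x$times)
})

test_that("inverse Gaussian sampler matches its first two moments", {
  set.seed(14)
  v <- rinvgauss(2e5, mean = 1.2, shape = 500)
  expect_true(all(v > 0))
  expect_equal(mean(v), 1.2, tolerance = 0.005)
  expect_equal(sd(v), sqrt(1.2^3 / 500), tolerance = 0.02)
})
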