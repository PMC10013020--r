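#' Autoregressive coefficients from pole specifications
#'
#' Builds the coefficients `c(1), ..., c(p)` of the AR recursion whose
#' transfer function has the requested poles. Each element of `poles` is
#' either a single number (a real pole, signed modulus) or a pair
#' `c(modulus, phase_rad)` expanding to a complex-conjugate pole pair. Pole
#' placement is the standard way to impose oscillations at chosen
#' frequencies on simulated interval series: a conjugate pair at modulus
#' `rho` and phase `2 * pi * f` creates a spectral peak near the normalized
#' frequency `f` (cycles per interval).
#'
#' @param poles list of pole specifications; all moduli must be < 1
#'   (stationarity).
#' @return numeric vector of AR coefficients; roots of the corresponding
#'   characteristic polynomial reproduce the poles.
#' @examples
#' ar_coeffs_from_poles(list(c(0.8, 2 * pi * 0.1)))  # a1 ~ 1.294, a2 = -0.64
#' @export
ar_coeffs_from_poles <- function(poles) {
  if (!is.list(poles)) poles <- list(poles)
  roots <- complex(0)
  for (p in poles) {
    if (length(p) == 1) {
      if (abs(p) >= 1) stop("pole modulus must be < 1", call. = FALSE)
      roots <- c(roots, complex(real = p))
    } else if (length(p) == 2) {
      if (abs(p[1]) >= 1) stop("pole modulus must be < 1", call. = FALSE)
      z <- p[1] * exp(1i * p[2])
      roots <- c(roots, z, Conj(z))
    } else stop("each pole is a modulus or a (modulus, phase) pair",
                call. = FALSE)
  }
  # expand prod(z - r_i) = z^p + b1 z^(p-1) + ... + bp; AR coefficients -b
  b <- 1 + 0i
  for (r in roots) b <- c(b, 0) - c(0, r * b)
  a <- -Re(b[-1])
  if (max(abs(Im(b))) > 1e-10)
    stop("complex poles must come in conjugate pairs", call. = FALSE)
  a
}

#' Inverse Gaussian random deviates
#'
#' Samples from IG(mean, shape) by the transformation method (one chi-square
#' deviate plus a uniform branch choice per draw).
#'
#' @param n number of draws.
#' @param mean distribution mean (s).
#' @param shape shape parameter lambda (s); variance is `mean^3 / shape`.
#' @return numeric vector of positive deviates.
#' @export
rinvgauss <- function(n, mean, shape) {
  if (any(mean <= 0) || any(shape <= 0))
    stop("mean and shape must be > 0", call. = FALSE)
  y <- rchisq(n, df = 1)
  x <- mean + (mean^2 * y - mean * sqrt(4 * mean * shape * y +
                                          mean^2 * y^2)) / (2 * shape)
  u <- runif(n)
  ifelse(u <= mean / (mean + x), x, mean^2 / x)
}

#' Renewal point processes
#'
#' Generates a point process with i.i.d. inter-event intervals drawn from an
#' exponential (a homogeneous Poisson process), Gaussian, or inverse
#' Gaussian distribution. Gaussian draws are resampled until positive so
#' that event times stay strictly increasing; the fraction of resampled
#' draws is recorded in the attribute `"truncation_frac"`.
#'
#' @param n_events number of events (the series starts at time 0).
#' @param dist interval distribution.
#' @param rate exponential rate (events/s).
#' @param mean,sd Gaussian interval mean and standard deviation (s).
#' @param ig_mean,shape inverse Gaussian mean and shape (s).
#' @param seed integer seed.
#' @param label series label.
#' @return an `event_series` with exactly `n_events` events.
#' @export
simulate_renewal <- function(n_events,
                             dist = c("exponential", "gaussian",
                                      "inverse_gaussian"),
                             rate = 1, mean = 1, sd = 0.2,
                             ig_mean = 1, shape = 600,
                             seed = NULL, label = "X") {
  dist <- match.arg(dist)
  n_events <- as.integer(n_events)
  if (n_events < 2) stop("n_events must be >= 2", call. = FALSE)
  m <- n_events - 1L
  trunc_frac <- 0
  w <- with_seed(seed, switch(
    dist,
    exponential = rexp(m, rate = rate),
    gaussian = {
      if (sd <= 0) stop("sd must be > 0", call. = FALSE)
      v <- rnorm(m, mean, sd)
      n_redraw <- 0
      while (any(v <= 0)) {
        bad <- v <= 0
        n_redraw <- n_redraw + sum(bad)
        v[bad] <- rnorm(sum(bad), mean, sd)
      }
      trunc_frac <- n_redraw / (m + n_redraw)
      v
    },
    inverse_gaussian = rinvgauss(m, ig_mean, shape)))
  out <- event_series(c(0, cumsum(w)), label = label)
  attr(out, "truncation_frac") <- trunc_frac
  out
}

#' History-dependent inverse Gaussian (HDIG) model parameters
#'
#' The HDIG heartbeat model draws each inter-event interval from an inverse
#' Gaussian density whose mean follows an autoregression on the previous
#' intervals. The AR part is applied to deviations from `theta0`, so the
#' stationary mean interval equals `theta0` exactly while the pole placement
#' (and hence the spectral content of the interval series) is as specified.
#' The default parameterization reproduces heart-period variability with
#' very-low-, low- and high-frequency oscillations: conjugate pole pairs at
#' (0.8, +/- 2*pi*0.1) and (0.92, +/- 2*pi*0.25) plus a real pole 0.6, with
#' `theta0` = 1 s and shape `lambda_shape` = 600 s.
#'
#' @param theta0 mean interval (s).
#' @param poles pole specification passed to [ar_coeffs_from_poles()]
#'   (ignored when `theta` is given).
#' @param theta explicit AR coefficients (must be stable).
#' @param lambda_shape inverse Gaussian shape parameter (s).
#' @return an object of class `hdig_params` with `theta0`, `theta`,
#'   `lambda_shape`, `p`.
#' @export
hdig_params <- function(theta0 = 1,
                        poles = list(c(0.8, 2 * pi * 0.1),
                                     c(0.92, 2 * pi * 0.25),
                                     0.6),
                        theta = NULL, lambda_shape = 600) {
  if (is.null(theta)) theta <- ar_coeffs_from_poles(poles)
  if (length(theta) > 0) {
    r <- Mod(polyroot(c(-rev(theta), 1)))
    if (any(r >= 1)) stop("unstable AR coefficients", call. = FALSE)
  }
  if (theta0 <= 0 || lambda_shape <= 0)
    stop("theta0 and lambda_shape must be > 0", call. = FALSE)
  structure(list(theta0 = theta0, theta = theta, lambda_shape = lambda_shape,
                 p = length(theta)),
            class = "hdig_params")
}

#' Simulate an HDIG point process
#'
#' Sequentially draws inter-event intervals `w[i] ~ IG(mu[i], lambda)` with
#' `mu[i] = theta0 + sum_j theta[j] * (w[i-j] - theta0)`, initialized at
#' `theta0`. A burn-in stretch is discarded so the reported series is
#' approximately stationary. Should an extreme excursion push `mu[i]` to or
#' below zero, it is clamped at `0.1 * theta0` to keep the density defined
#' (occurrences are counted in the attribute `"n_clamped"`).
#'
#' @param params an [hdig_params()] object.
#' @param n_events number of events.
#' @param seed integer seed.
#' @param burn_in warm-up intervals discarded before collecting the series.
#' @param label series label.
#' @return an `event_series` starting at 0 with `n_events` events.
#' @export
simulate_hdig <- function(params = hdig_params(), n_events, seed = NULL,
                          burn_in = 200, label = "X") {
  stopifnot(inherits(params, "hdig_params"))
  n_events <- as.integer(n_events)
  if (n_events < 2) stop("n_events must be >= 2", call. = FALSE)
  total <- burn_in + n_events - 1L
  p <- params$p
  th <- params$theta
  th0 <- params$theta0
  w <- with_seed(seed, {
    out <- numeric(total)
    hist <- rep(th0, max(p, 1))            # w[i] = theta0 for i <= p
    n_clamped <- 0
    for (i in seq_len(total)) {
      mu <- th0 + if (p > 0) sum(th * (hist[seq_len(p)] - th0)) else 0
      if (mu <= 0) {
        mu <- 0.1 * th0
        n_clamped <- n_clamped + 1
      }
      out[i] <- rinvgauss(1, mu, params$lambda_shape)
      if (p > 0) hist <- c(out[i], hist[seq_len(max(p - 1, 1))])
    }
    attr(out, "n_clamped") <- n_clamped
    out
  })
  kept <- w[(burn_in + 1):total]
  out <- event_series(c(0, cumsum(kept)), label = label)
  attr(out, "n_clamped") <- attr(w, "n_clamped")
  out
}

#' Innovation standard deviation for a target AR(2) output variance
#'
#' For the stationary AR(2) process `tau[i] = a1 tau[i-1] + a2 tau[i-2] + u[i]`,
#' returns the innovation standard deviation that yields a process standard
#' deviation of exactly `sigma_pat`, from the closed-form stationary
#' variance `var(tau) = sigma_u^2 (1 - a2) / ((1 + a2) ((1 - a2)^2 - a1^2))`.
#'
#' @param a1,a2 AR(2) coefficients (must be stationary).
#' @param sigma_pat target process standard deviation (s).
#' @return innovation standard deviation (s).
#' @export
calibrate_innovation_sd <- function(a1, a2, sigma_pat) {
  if (abs(a2) >= 1 || a1 + a2 >= 1 || a2 - a1 >= 1)
    stop("AR(2) coefficients are not stationary", call. = FALSE)
  if (sigma_pat <= 0) stop("sigma_pat must be > 0", call. = FALSE)
  sigma_pat * sqrt((1 + a2) * ((1 - a2)^2 - a1^2) / (1 - a2))
}

#' Pulse-arrival delay model parameters
#'
#' The delay between a heartbeat and the arrival of its pressure wave at the
#' periphery (pulse arrival time, PAT) is modelled as `a0` plus a
#' second-order autoregression on the previous delay deviations, driven by
#' Gaussian innovations calibrated so the delay standard deviation equals
#' `sigma_pat`. The default poles (0.8, +/- 2*pi*0.1) impose a stochastic
#' oscillation near 0.1 cycles/beat; the default mean delay is 300 ms.
#'
#' @param sigma_pat target delay standard deviation (s); in the coupled
#'   simulation it acts as the de-coupling parameter (10 to 235 ms).
#' @param a0 mean delay (s).
#' @param poles AR(2) pole specification (one conjugate pair).
#' @return an object of class `pat_params` with `a0`, `a1`, `a2`,
#'   `sigma_pat`, `sigma_u`.
#' @export
pat_params <- function(sigma_pat, a0 = 0.3,
                       poles = list(c(0.8, 2 * pi * 0.1))) {
  a <- ar_coeffs_from_poles(poles)
  if (length(a) != 2) stop("delay model must be AR(2)", call. = FALSE)
  structure(list(a0 = a0, a1 = a[1], a2 = a[2], sigma_pat = sigma_pat,
                 sigma_u = calibrate_innovation_sd(a[1], a[2], sigma_pat)),
            class = "pat_params")
}

# stationary AR(2) deviations with burn-in, innovations sd sigma_u
ar2_deviations <- function(n, a1, a2, sigma_u, burn_in = 200) {
  total <- n + burn_in
  u <- rnorm(total, 0, sigma_u)
  d <- numeric(total)
  d[1] <- u[1]
  d[2] <- a1 * d[1] + u[2]
  for (i in 3:total) d[i] <- a1 * d[i - 1] + a2 * d[i - 2] + u[i]
  d[(burn_in + 1):total]
}

#' Simulate pulse arrival times coupled to a heartbeat process
#'
#' Produces the companion process `y[i] = x[i] + tau[i]`, where the
#' propagation delays `tau` follow the AR(2) model of [pat_params()]. Small
#' `sigma_pat` makes `y` an almost deterministic copy of `x` (strong
#' coupling); large `sigma_pat` decouples the two processes. With wide delay
#' variability individual delays can become non-positive; they are kept (and
#' counted in the attribute `"n_nonpositive_delays"`) unless
#' `clip_delays = TRUE`, which clips them to `clip_at` seconds with a
#' warning. An error is raised only if the resulting series is not strictly
#' increasing or collides with an event of `x`.
#'
#' @param x heartbeat `event_series` (for example from [simulate_hdig()]).
#' @param params a [pat_params()] object.
#' @param seed integer seed.
#' @param clip_delays clip non-positive delays instead of keeping them.
#' @param clip_at clipping value (s).
#' @param label series label.
#' @return an `event_series` of the same length as `x`.
#' @export
simulate_pat_process <- function(x, params, seed = NULL, clip_delays = FALSE,
                                 clip_at = 1e-3, label = "Y") {
  stopifnot(inherits(x, "event_series"), inherits(params, "pat_params"))
  n <- n_events(x)
  tau <- params$a0 + with_seed(seed, ar2_deviations(n, params$a1, params$a2,
                                                    params$sigma_u))
  n_nonpos <- sum(tau <= 0)
  if (n_nonpos > 0 && clip_delays) {
    warning(n_nonpos, " non-positive delays clipped to ", clip_at, " s")
    tau[tau <= 0] <- clip_at
  }
  yt <- x$times + tau
  if (any(diff(yt) <= 0))
    stop("delay variability too large: arrival times not strictly increasing",
         call. = FALSE)
  if (any(yt %in% x$times))
    stop("arrival time coincides with a heartbeat time", call. = FALSE)
  out <- event_series(yt, label = label)
  attr(out, "n_nonpositive_delays") <- n_nonpos
  out
}

#' Simulate two point processes sharing a common low-frequency driver
#'
#' Variant of the coupled simulation in which the same delay realization
#' drives both processes. The heartbeat intervals follow an HDIG model of
#' order 3 whose poles (a real pole 0.92 plus a conjugate pair at
#' (0.92, +/- 2*pi*0.25)) place oscillatory activity outside the
#' low-frequency band; the low-frequency component is then injected by
#' adding `2 * tau[i]` to each interval, with `tau` the AR(2) delay process
#' of [pat_params()]. The arrival process is `y[i] = x[i] + tau[i]` with the
#' identical `tau` realization, so `sigma_pat` scales the variance of the
#' shared component and acts as a coupling parameter. Intervals pushed to or
#' below zero by extreme negative delays are clamped at `0.05 * theta0`
#' (counted in the attribute `"n_clamped_intervals"`).
#'
#' @param sigma_pat delay standard deviation (s), the coupling strength.
#' @param n_events number of events in each series.
#' @param seed integer seed.
#' @param theta0,lambda_shape HDIG mean interval and shape (s).
#' @param a0 mean delay (s).
#' @return list with `event_series` elements `x` and `y`.
#' @export
simulate_common_driver <- function(sigma_pat, n_events, seed = NULL,
                                   theta0 = 1, lambda_shape = 600, a0 = 0.3) {
  n_events <- as.integer(n_events)
  if (n_events < 2) stop("n_events must be >= 2", call. = FALSE)
  hp <- hdig_params(theta0 = theta0,
                    poles = list(0.92, c(0.92, 2 * pi * 0.25)),
                    lambda_shape = lambda_shape)
  pp <- pat_params(sigma_pat, a0 = a0)
  x0 <- simulate_hdig(hp, n_events, seed = derive_seed(seed, 1L), label = "X")
  tau <- pp$a0 + with_seed(derive_seed(seed, 2L),
                           ar2_deviations(n_events, pp$a1, pp$a2, pp$sigma_u))
  w <- diff(x0$times) + 2 * tau[seq_len(n_events - 1L)]
  # keep both series strictly increasing under extreme negative delays:
  # w[i] must stay positive and exceed tau[i] - tau[i+1]
  floor_w <- pmax(0.05 * theta0,
                  tau[seq_len(n_events - 1L)] - tau[-1L] + 0.01 * theta0)
  n_clamped <- sum(w < floor_w)
  w <- pmax(w, floor_w)
  x <- event_series(c(0, cumsum(w)), label = "X")
  yt <- x$times + tau
  if (any(yt %in% x$times))
    stop("arrival time coincides with a heartbeat time", call. = FALSE)
  y <- event_series(yt, label = "Y")
  attr(x, "n_clamped_intervals") <- n_clamped
  list(x = x, y = y)
}
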