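# Small deterministic fixtures shared across test files.

# a coupled heartbeat / pulse-arrival pair from the second simulation scenario
sim2_fixture <- function(sigma_pat = 0.085, n_events = 300, seed = 42) {
  x <- simulate_hdig(hdig_params(), n_events, seed = seed)
  y <- simulate_pat_process(x, pat_params(sigma_pat), seed = seed + 1)
  list(x = x, y = y)
}

# an uncoupled pair of unit-rate Poisson processes
poisson_fixture <- function(n_events = 300, seed = 7) {
  x <- simulate_renewal(n_events, "exponential", rate = 1, seed = seed)
  y <- simulate_renewal(n_events, "exponential", rate = 1, seed = seed + 1)
  resolve_simultaneous(x, y, jitter = TRUE, seed = seed + 2)
}
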