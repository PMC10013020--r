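#' Surrogate configuration
#'
#' Selects the engine used to generate data consistent with the uncoupled
#' null hypothesis and its parameters.
#'
#' Engines:
#' * `"local_permutation"` — permutes the source blocks of the joint history
#'   embeddings among rows with similar target histories, testing
#'   independence of the target's present from the source history given the
#'   target history while keeping the target/source history relation.
#' * `"shuffle"` — random permutation of the inter-event intervals,
#'   preserving their distribution.
#' * `"iaaft"` — iterative amplitude-adjusted Fourier transform on the
#'   interval series, preserving distribution and power spectrum.
#' * `"jodi"` — autocorrelation-preserving permutation of the intervals
#'   (amplitude distribution and lag-1..5 autocorrelation preserved).
#'
#' @param method surrogate engine.
#' @param M number of surrogate pairs.
#' @param seed integer seed for surrogate generation (or `NULL` to derive
#'   one from the estimator seed).
#' @param n_perm_neighbors neighborhood size of the local permutation.
#' @param max_iter iteration cap for the IAAFT loop / annealing sweeps.
#' @param apply_to `"source"` (surrogate each direction's source process) or
#'   `"both"` (surrogate the two processes independently); interval-based
#'   engines only.
#' @return an object of class `surrogate_config`.
#' @export
surrogate_config <- function(method = c("local_permutation", "shuffle",
                                        "iaaft", "jodi"),
                             M = 100, seed = NULL, n_perm_neighbors = 10,
                             max_iter = 100, apply_to = c("source", "both")) {
  method <- match.arg(method)
  M <- as.integer(M)
  n_perm_neighbors <- as.integer(n_perm_neighbors)
  max_iter <- as.integer(max_iter)
  if (M < 1 || n_perm_neighbors < 1 || max_iter < 1)
    stop("M, n_perm_neighbors and max_iter must all be >= 1", call. = FALSE)
  structure(list(method = method, M = M, seed = seed,
                 n_perm_neighbors = n_perm_neighbors, max_iter = max_iter,
                 apply_to = match.arg(apply_to)),
            class = "surrogate_config")
}

#' Local permutation of joint history embeddings
#'
#' Replaces the source block (last `l` columns) of every row of a joint
#' embedding matrix with the source block of a row drawn from its
#' `n_perm_neighbors` nearest rows in target-block max-norm distance. The
#' replacement is a bijection without fixed points, so the multiset of
#' source blocks is preserved exactly and target blocks are untouched. This
#' realizes the null hypothesis that the target's present is independent of
#' the source history given the target history.
#'
#' @param joint an `embedding_set` with scope `"joint"`, or a numeric matrix
#'   with `2 * l` columns (target coordinates first).
#' @param l embedding length (taken from the `embedding_set` if omitted).
#' @param n_perm_neighbors neighborhood size.
#' @param seed integer seed.
#' @return object of the same type as `joint` with permuted source blocks.
#' @export
local_permutation <- function(joint, l = NULL, n_perm_neighbors = 10,
                              seed = NULL) {
  is_set <- inherits(joint, "embedding_set")
  if (is_set) {
    if (joint$scope != "joint")
      stop("local permutation needs a joint-scope embedding set", call. = FALSE)
    if (is.null(l)) l <- joint$l
  }
  m <- embedding_matrix(joint)
  l <- check_l(l)
  if (ncol(m) != 2L * l)
    stop("joint embedding must have 2 * l columns", call. = FALSE)
  n <- nrow(m)
  if (n < n_perm_neighbors + 1)
    stop("need at least n_perm_neighbors + 1 rows", call. = FALSE)
  tb <- m[, seq_len(l), drop = FALSE]
  nb <- knn_neighbor_indices(tb, tb, n_perm_neighbors, TRUE)
  assign <- with_seed(seed, {
    a <- integer(n)
    used <- logical(n)
    for (i in sample.int(n)) {
      cand <- nb[i, sample.int(n_perm_neighbors)]
      cand <- cand[!used[cand]]
      if (length(cand)) {
        pick <- cand[1]
      } else {
        avail <- which(!used & seq_len(n) != i)
        pick <- if (length(avail)) avail[sample.int(length(avail), 1)] else i
      }
      a[i] <- pick
      used[pick] <- TRUE
    }
    for (i in which(a == seq_len(n))) {     # remove rare forced fixed points
      j <- which(seq_len(n) != i & a != i)
      j <- j[sample.int(length(j), 1)]
      tmp <- a[j]; a[j] <- a[i]; a[i] <- tmp
    }
    a
  })
  m[, l + seq_len(l)] <- m[assign, l + seq_len(l), drop = FALSE]
  if (is_set) {
    joint$samples <- m
    joint
  } else m
}

#' Interval-series surrogates
#'
#' All three engines return a reordering of the original inter-event
#' intervals, so the amplitude multiset, the total duration and the start
#' time are preserved exactly. They differ in what else is preserved:
#' `surrogate_shuffle()` preserves only the distribution;
#' `surrogate_iaaft()` additionally matches the power spectrum via the
#' iterative amplitude-adjusted Fourier transform (spectrum step in the
#' Fourier domain alternating with rank-ordering to the original
#' amplitudes, stopped at rank convergence or `max_iter`);
#' `surrogate_jodi()` matches the lag-1..5 autocorrelations by greedy
#' pairwise-swap descent on the summed squared autocorrelation discrepancy,
#' stopped at `tol` or after `max_iter` sweeps.
#'
#' @param iv an `interval_series` (IAAFT and the autocorrelation engine
#'   require at least 8 intervals).
#' @param seed integer seed; fixed seed gives a bit-identical surrogate.
#' @param max_iter IAAFT iteration cap / number of annealing sweeps.
#' @param max_lag number of autocorrelation lags to match.
#' @param tol convergence tolerance on the summed squared autocorrelation
#'   discrepancy.
#' @return an `interval_series`.
#' @export
surrogate_shuffle <- function(iv, seed = NULL) {
  stopifnot(inherits(iv, "interval_series"))
  interval_series(with_seed(seed, sample(iv$intervals)),
                  start_time = iv$start_time, label = iv$label)
}

#' @rdname surrogate_shuffle
#' @export
surrogate_iaaft <- function(iv, seed = NULL, max_iter = 100) {
  stopifnot(inherits(iv, "interval_series"))
  x <- iv$intervals
  n <- length(x)
  if (n < 8) stop("IAAFT needs at least 8 intervals", call. = FALSE)
  s <- sort(x)
  A <- Mod(fft(x))
  cur <- with_seed(seed, sample(x))
  prev_rank <- NULL
  for (it in seq_len(max_iter)) {
    y <- Re(fft(A * exp(1i * Arg(fft(cur))), inverse = TRUE)) / n
    r <- rank(y, ties.method = "first")
    cur <- s[r]
    if (identical(r, prev_rank)) break
    prev_rank <- r
  }
  interval_series(cur, start_time = iv$start_time, label = iv$label)
}

#' @rdname surrogate_shuffle
#' @export
surrogate_jodi <- function(iv, seed = NULL, max_iter = 100, max_lag = 5,
                           tol = 1e-4) {
  stopifnot(inherits(iv, "interval_series"))
  x <- iv$intervals
  n <- length(x)
  if (n < 8) stop("need at least 8 intervals", call. = FALSE)
  max_lag <- min(as.integer(max_lag), n - 1L)
  perm <- with_seed(seed,
                    acf_swap_descent(x, sample.int(n), max_lag,
                                     as.integer(max_iter), tol))
  interval_series(x[perm], start_time = iv$start_time, label = iv$label)
}

#' MIR distribution over surrogate pairs
#'
#' Generates `M` surrogate pairs under the uncoupled null hypothesis and
#' returns the MIR estimated on each, in nats/s. For the interval-based
#' engines the surrogate event series are rebuilt from the surrogated
#' interval series of each direction's source process (or of both processes
#' with `apply_to = "both"`). For the local permutation engine no surrogate
#' event series exists: each surrogate MIR is the sum of the two directed
#' rates recomputed after independently permuting the source blocks of each
#' direction's joint embedding set, with the random-time reference sets held
#' fixed.
#'
#' @param x,y `event_series` objects.
#' @param cfg an [estimator_config()].
#' @param scfg a [surrogate_config()].
#' @return numeric vector of `M` MIR values.
#' @export
surrogate_mir_values <- function(x, y, cfg = estimator_config(),
                                 scfg = surrogate_config()) {
  stopifnot(inherits(cfg, "estimator_config"),
            inherits(scfg, "surrogate_config"))
  sseed <- if (is.null(scfg$seed)) derive_seed(cfg$seed, 9000L) else scfg$seed
  M <- scfg$M
  vals <- numeric(M)
  if (scfg$method == "local_permutation") {
    # streams 10/20 match mir(), so surrogates share the original estimate's
    # embeddings and random-time draws
    ctx_yx <- ter_context(x, y, cfg, stream = 10L)
    ctx_xy <- ter_context(y, x, cfg, stream = 20L)
    for (m in seq_len(M)) {
      p_yx <- local_permutation(ctx_yx$joint_x, l = cfg$l,
                                n_perm_neighbors = scfg$n_perm_neighbors,
                                seed = derive_seed(sseed, m))
      p_xy <- local_permutation(ctx_xy$joint_x, l = cfg$l,
                                n_perm_neighbors = scfg$n_perm_neighbors,
                                seed = derive_seed(sseed, M + m))
      vals[m] <- ter_from_context(ctx_yx, cfg, joint_x = p_yx)$value +
        ter_from_context(ctx_xy, cfg, joint_x = p_xy)$value
    }
    return(vals)
  }
  gen <- switch(scfg$method,
                shuffle = function(iv, sd) surrogate_shuffle(iv, seed = sd),
                iaaft = function(iv, sd)
                  surrogate_iaaft(iv, seed = sd, max_iter = scfg$max_iter),
                jodi = function(iv, sd)
                  surrogate_jodi(iv, seed = sd, max_iter = scfg$max_iter))
  ivx <- intervals(x)
  ivy <- intervals(y)
  for (m in seq_len(M)) {
    xs <- events_from_intervals(gen(ivx, derive_seed(sseed, m)))
    ys <- events_from_intervals(gen(ivy, derive_seed(sseed, M + m)))
    vals[m] <- if (scfg$apply_to == "source") {
      ter(x, ys, cfg, .stream = 10L)$value + ter(y, xs, cfg, .stream = 20L)$value
    } else {
      mir(xs, ys, cfg)$mir
    }
  }
  vals
}
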