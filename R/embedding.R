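#' History embeddings of point processes
#'
#' The past of a point process observed at a time point is approximated by a
#' finite-dimensional history embedding built from inter-event intervals.
#' Observed at a target event `x[i]`, the target history is the `l` most
#' recent target inter-event intervals (most recent first) and the source
#' history is the time from the most recent source event `y[p]` strictly
#' before `x[i]` back to `x[i]`, followed by the `l - 1` source intervals
#' ending at `y[p]`. Observed at an arbitrary time `u`, each history is the
#' time since the most recent event followed by `l - 1` preceding intervals.
#'
#' `embed_at_events()` samples the embeddings at the target events (the
#' distribution `p_x`); `embed_at_times()` samples them at supplied time
#' points (the distribution `p_u`). Both return the joint embedding (2l
#' columns, target coordinates first) and the target-only embedding (the
#' first l columns) restricted to sampling points where the full joint
#' embedding exists; points lacking history are dropped.
#'
#' @param target,source `event_series` objects with no shared timestamp.
#' @param l embedding length per process (number of intervals), >= 1.
#' @param u_times numeric vector of candidate observation times.
#' @return a list with elements `joint` and `target_only`, each an
#'   `embedding_set`: a list carrying `samples` (matrix), `l`, `kind`
#'   (`"at_target_events"` or `"at_random_times"`), `scope` and
#'   `sample_times`.
#' @examples
#' x <- event_series(c(1, 2, 3.5, 4))
#' y <- event_series(c(0.5, 2.6, 3.8))
#' embed_at_events(x, y, l = 2)$joint$samples
#' @export
embed_at_events <- function(target, source, l) {
  stopifnot(inherits(target, "event_series"), inherits(source, "event_series"))
  l <- check_l(l)
  if (length(intersect(target$times, source$times)) > 0)
    stop("simultaneous events between target and source; see resolve_simultaneous()",
         call. = FALSE)
  tx <- target$times
  ty <- source$times
  p <- findInterval(tx, ty)                 # most recent source event before x_i
  idx <- which(seq_along(tx) > l & p >= l)  # full target and source histories
  if (length(idx) == 0)
    stop("no target event has a full joint history for l = ", l, call. = FALSE)
  pu <- p[idx]
  m <- matrix(0, length(idx), 2L * l)
  for (k in seq_len(l))                     # target intervals, most recent first
    m[, k] <- tx[idx - k + 1L] - tx[idx - k]
  m[, l + 1L] <- tx[idx] - ty[pu]           # time from last source event to x_i
  if (l > 1) for (k in 2:l)                 # source intervals ending at y_p
    m[, l + k] <- ty[pu - k + 2L] - ty[pu - k + 1L]
  make_embedding_pair(m, l, "at_target_events", tx[idx])
}

#' @rdname embed_at_events
#' @export
embed_at_times <- function(target, source, l, u_times) {
  stopifnot(inherits(target, "event_series"), inherits(source, "event_series"))
  l <- check_l(l)
  u <- as.numeric(u_times)
  tx <- target$times
  ty <- source$times
  u <- u[!(u %in% tx) & !(u %in% ty)]  # u must differ from every event time
  xp <- findInterval(u, tx)
  yp <- findInterval(u, ty)
  ok <- xp >= l & yp >= l                   # full histories at u
  u <- u[ok]; xp <- xp[ok]; yp <- yp[ok]
  if (length(u) == 0)
    stop("no supplied time point has a full joint history for l = ", l,
         call. = FALSE)
  m <- matrix(0, length(u), 2L * l)
  m[, 1L] <- u - tx[xp]
  if (l > 1) for (k in 2:l)
    m[, k] <- tx[xp - k + 2L] - tx[xp - k + 1L]
  m[, l + 1L] <- u - ty[yp]
  if (l > 1) for (k in 2:l)
    m[, l + k] <- ty[yp - k + 2L] - ty[yp - k + 1L]
  make_embedding_pair(m, l, "at_random_times", u)
}

#' Draw random observation times for the cross-entropy reference set
#'
#' Samples `n_u` time points uniformly from the window in which the joint
#' history embeddings of both processes are defined (strictly after the
#' `l`-th event of either series, up to the end of the record), so that every
#' drawn point yields a full embedding row. The default `n_u` equals the
#' number of usable target events, matching the estimator convention that the
#' random-time sample has the same size as the target-event sample.
#'
#' @inheritParams embed_at_events
#' @param n_u number of time points (default: number of usable target events).
#' @param seed integer seed; fixed seed gives identical draws.
#' @return numeric vector of time points, sorted.
#' @export
sample_random_times <- function(target, source, l, n_u = NULL, seed = NULL) {
  stopifnot(inherits(target, "event_series"), inherits(source, "event_series"))
  l <- check_l(l)
  tx <- target$times
  ty <- source$times
  if (length(tx) < l + 1 || length(ty) < l)
    stop("series too short for embedding length l = ", l, call. = FALSE)
  lo <- max(tx[l], ty[l])
  hi <- max(tx[length(tx)], ty[length(ty)])
  if (!(hi > lo))
    stop("empty sampling window: no time at which both histories exist",
         call. = FALSE)
  if (is.null(n_u)) {
    p <- findInterval(tx, ty)
    n_u <- sum(seq_along(tx) > l & p >= l)
    if (n_u == 0)
      stop("no usable target event for l = ", l, call. = FALSE)
  }
  with_seed(seed, {
    u <- runif(n_u, lo, hi)
    bad <- u %in% tx | u %in% ty | u == lo  # measure-zero guard
    while (any(bad)) {
      u[bad] <- runif(sum(bad), lo, hi)
      bad <- u %in% tx | u %in% ty | u == lo
    }
    sort(u)
  })
}

# ---- internal helpers -------------------------------------------------------

check_l <- function(l) {
  l <- as.integer(l)
  if (length(l) != 1 || is.na(l) || l < 1)
    stop("l must be a positive integer", call. = FALSE)
  l
}

new_embedding_set <- function(samples, l, kind, scope, sample_times) {
  structure(list(samples = samples, l = l, kind = kind, scope = scope,
                 sample_times = sample_times),
            class = "embedding_set")
}

make_embedding_pair <- function(m, l, kind, sample_times) {
  list(joint = new_embedding_set(m, l, kind, "joint", sample_times),
       target_only = new_embedding_set(m[, seq_len(l), drop = FALSE], l, kind,
                                       "target_only", sample_times))
}

#' @export
print.embedding_set <- function(x, ...) {
  cat(sprintf("embedding_set: %d samples x %d coords (l = %d, %s, %s)\n",
              nrow(x$samples), ncol(x$samples), x$l, x$scope, x$kind))
  invisible(x)
}

# matrix view used by the entropy estimators
embedding_matrix <- function(x) {
  if (inherits(x, "embedding_set")) x$samples else as.matrix(x)
}
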