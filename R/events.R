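#' Event series
#'
#' An `event_series` stores the occurrence times of one point process:
#' strictly increasing timestamps in seconds. It is the realization of a
#' process fully described by its event times (heartbeats, systolic peaks,
#' neural spikes, ...).
#'
#' @param times numeric vector of strictly increasing timestamps (seconds),
#'   at least two events.
#' @param label free-text label for the process.
#' @return an object of class `event_series` with elements `times` and
#'   `label`.
#' @examples
#' x <- event_series(c(0, 1, 2.5), "X")
#' n_events(x)
#' event_rate(x)
#' @export
event_series <- function(times, label = "X") {
  times <- as.numeric(times)
  if (length(times) < 2)
    stop("an event series needs at least 2 events", call. = FALSE)
  if (anyNA(times) || any(!is.finite(times)))
    stop("event times must be finite", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("event times must be strictly increasing", call. = FALSE)
  structure(list(times = times, label = as.character(label)[1]),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("event_series '%s': %d events over %.3f s (mean rate %.3f events/s)\n",
              x$label, n_events(x), duration(x), event_rate(x)))
  invisible(x)
}

#' Number of events, duration, and mean event rate
#'
#' `n_events()` returns the event count N, `duration()` the span T between
#' first and last event (seconds), and `event_rate()` the mean rate N / T
#' (events/s) used as the multiplicative factor of the transfer entropy rate.
#'
#' @param x an `event_series`.
#' @return a scalar.
#' @export
n_events <- function(x) length(x$times)

#' @rdname n_events
#' @export
duration <- function(x) x$times[length(x$times)] - x$times[1]

#' @rdname n_events
#' @export
event_rate <- function(x) n_events(x) / duration(x)

#' Interval series
#'
#' An `interval_series` stores the inter-event intervals of a point process
#' together with the start time, so that the original event series can be
#' rebuilt exactly. Surrogate engines operate on interval series.
#'
#' @param intervals numeric vector of strictly positive durations (seconds).
#' @param start_time timestamp of the first event (seconds).
#' @param label free-text label.
#' @return an object of class `interval_series`.
#' @seealso [intervals()], [events_from_intervals()]
#' @export
interval_series <- function(intervals, start_time = 0, label = "X") {
  intervals <- as.numeric(intervals)
  if (length(intervals) < 1)
    stop("need at least one interval", call. = FALSE)
  if (anyNA(intervals) || any(!is.finite(intervals)) || any(intervals <= 0))
    stop("all intervals must be finite and > 0", call. = FALSE)
  structure(list(start_time = as.numeric(start_time)[1], intervals = intervals,
                 label = as.character(label)[1]),
            class = "interval_series")
}

#' @export
print.interval_series <- function(x, ...) {
  cat(sprintf("interval_series '%s': %d intervals, start %.3f s, mean %.4f s, sd %.4f s\n",
              x$label, length(x$intervals), x$start_time,
              mean(x$intervals), stats::sd(x$intervals)))
  invisible(x)
}

#' Convert between event and interval representations
#'
#' `intervals()` differences an event series into its inter-event intervals;
#' `events_from_intervals()` rebuilds the event series by cumulative
#' summation from the stored start time. The round trip is the identity.
#'
#' @param series an `event_series`.
#' @param iv an `interval_series`.
#' @return an `interval_series`, respectively an `event_series`.
#' @examples
#' s <- event_series(c(0, 1, 2.5))
#' iv <- intervals(s)
#' all.equal(events_from_intervals(iv)$times, s$times)
#' @export
intervals <- function(series) {
  stopifnot(inherits(series, "event_series"))
  interval_series(diff(series$times), start_time = series$times[1],
                  label = series$label)
}

#' @rdname intervals
#' @export
events_from_intervals <- function(iv) {
  stopifnot(inherits(iv, "interval_series"))
  event_series(iv$start_time + c(0, cumsum(iv$intervals)), label = iv$label)
}

#' Resolve simultaneous events between two series
#'
#' The estimator assumes that no event of one process coincides with an event
#' of the other (so that the instantaneous information exchange term is
#' identically zero). By default shared timestamps raise an error; with
#' `jitter = TRUE` the colliding events of `y` are displaced by a seeded
#' uniform offset in +/- `amount` seconds, which is appropriate for real data
#' recorded on a shared sampling grid.
#'
#' @param x,y `event_series` objects.
#' @param jitter apply a deterministic seeded jitter instead of failing.
#' @param amount jitter half-width in seconds.
#' @param seed integer seed for the jitter.
#' @return list with elements `x` and `y` (possibly jittered).
#' @export
resolve_simultaneous <- function(x, y, jitter = FALSE, amount = 1e-6,
                                 seed = NULL) {
  shared <- intersect(x$times, y$times)
  if (length(shared) == 0) return(list(x = x, y = y))
  if (!jitter)
    stop(sprintf("%d simultaneous events between '%s' and '%s'; set jitter = TRUE to displace them",
                 length(shared), x$label, y$label), call. = FALSE)
  ty <- y$times
  hit <- ty %in% shared
  ty[hit] <- ty[hit] + with_seed(seed, runif(sum(hit), -amount, amount))
  list(x = x, y = event_series(sort(ty), label = y$label))
}

#' Read and write event and interval files
#'
#' Event files are single-column ASCII text, one timestamp (seconds) per
#' line; lines starting with `#` are comments. Interval files use the same
#' format with a header line `# start=<t0>` carrying the start time.
#'
#' @param path file path.
#' @param label label for the resulting series (default: file name).
#' @param x an `event_series`.
#' @param iv an `interval_series`.
#' @return `read_events()` an `event_series`; `read_intervals()` an
#'   `interval_series`; the writers return their input invisibly.
#' @export
read_events <- function(path, label = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  times <- suppressWarnings(as.numeric(lines))
  if (anyNA(times))
    stop("non-numeric line in event file ", path, call. = FALSE)
  event_series(times, label = if (is.null(label)) basename(path) else label)
}

#' @rdname read_events
#' @export
write_events <- function(x, path) {
  stopifnot(inherits(x, "event_series"))
  writeLines(c(sprintf("# event series '%s'", x$label),
               format(x$times, digits = 17, scientific = FALSE, trim = TRUE)),
             path)
  invisible(x)
}

#' @rdname read_events
#' @export
read_intervals <- function(path, label = NULL) {
  lines <- trimws(readLines(path))
  start <- 0
  hdr <- grep("^#\\s*start=", lines, value = TRUE)
  if (length(hdr)) start <- as.numeric(sub("^#\\s*start=", "", hdr[1]))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  iv <- suppressWarnings(as.numeric(lines))
  if (anyNA(iv))
    stop("non-numeric line in interval file ", path, call. = FALSE)
  interval_series(iv, start_time = start,
                  label = if (is.null(label)) basename(path) else label)
}

#' @rdname read_events
#' @export
write_intervals <- function(iv, path) {
  stopifnot(inherits(iv, "interval_series"))
  writeLines(c(sprintf("# start=%s",
                       format(iv$start_time, digits = 17, scientific = FALSE)),
               format(iv$intervals, digits = 17, scientific = FALSE, trim = TRUE)),
             path)
  invisible(iv)
}
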