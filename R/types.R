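#' Timestamped event series
#'
#' Container for detected seizure events: one row per event with its
#' timestamp, the detector's estimated probability of being a true event,
#' and whether the event was also recorded in the participant's diary.
#'
#' @param timestamps event times, coercible to POSIXct (stored in UTC);
#'   must be non-decreasing.
#' @param probability per-event detection probability in \[0, 1\]
#'   (recycled; default 1).
#' @param reported logical, whether the event appears in the diary
#'   (recycled; default FALSE).
#'
#' @return A data frame of class \code{event_series} with columns
#'   \code{timestamp}, \code{probability}, \code{reported}.
#' @export
#' @examples
#' ev <- event_series(as.POSIXct("2020-01-01 09:00", tz = "UTC") + c(0, 3600))
#' n_events(ev)
event_series <- function(timestamps, probability = 1, reported = FALSE) {
  timestamps <- as.POSIXct(timestamps, tz = "UTC")
  n <- length(timestamps)
  probability <- rep_len(as.numeric(probability), n)
  reported <- rep_len(as.logical(reported), n)
  if (n > 1L && any(diff(as.numeric(timestamps)) < 0))
    stop("event timestamps must be non-decreasing")
  if (n > 0L && (any(!is.finite(probability)) ||
                 any(probability < 0 | probability > 1)))
    stop("event probabilities must lie in [0, 1]")
  structure(
    data.frame(timestamp = timestamps, probability = probability,
               reported = reported),
    class = c("event_series", "data.frame")
  )
}

#' Number of events in an event series
#' @param x an \code{event_series}.
#' @return integer count.
#' @export
n_events <- function(x) nrow(x)

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> %d events", nrow(x)))
  if (nrow(x) > 0)
    cat(sprintf(" from %s to %s",
                format(x$timestamp[1], "%Y-%m-%d"),
                format(x$timestamp[nrow(x)], "%Y-%m-%d")))
  cat(sprintf("; %d reported\n", sum(x$reported)))
  invisible(x)
}

#' Regular-grid rate series
#'
#' A numeric series on a regular hourly or daily grid with an explicit
#' missingness mask, used for hourly IED rates and daily seizure counts.
#'
#' @param start POSIXct (or coercible) timestamp of the first sample (UTC).
#' @param step grid step, \code{"hour"} or \code{"day"}.
#' @param values numeric vector of rates/counts.
#' @param missing logical mask, same length as \code{values}; TRUE marks
#'   samples falling in recording gaps. Defaults to \code{!is.finite(values)}.
#'
#' @return An object of class \code{rate_series}.
#' @export
rate_series <- function(start, step = c("hour", "day"), values,
                        missing = NULL) {
  step <- match.arg(step)
  start <- as.POSIXct(start, tz = "UTC")
  values <- as.numeric(values)
  if (is.null(missing)) missing <- !is.finite(values)
  missing <- as.logical(missing)
  if (length(missing) != length(values))
    stop("missing mask length must equal values length")
  if (any(!is.finite(values[!missing])))
    stop("values must be finite where not missing")
  structure(list(start = start, step = step, values = values,
                 missing = missing),
            class = "rate_series")
}

step_seconds <- function(x) switch(x$step, hour = 3600, day = 86400)

#' Sample timestamps of a rate series
#' @param x a \code{rate_series}.
#' @return POSIXct vector, one per sample.
#' @export
rs_times <- function(x) x$start + (seq_along(x$values) - 1) * step_seconds(x)

#' Calendar dates of a daily rate series
#' @param x a daily \code{rate_series}.
#' @return Date vector, one per sample.
#' @export
rs_dates <- function(x) {
  if (x$step != "day") stop("rs_dates() requires a daily series")
  as.Date(x$start) + (seq_along(x$values) - 1)
}

#' @export
length.rate_series <- function(x) length(x$values)

#' @export
print.rate_series <- function(x, ...) {
  cat(sprintf("<rate_series> %d %sly samples from %s; %d missing\n",
              length(x$values), x$step, format(x$start, "%Y-%m-%d %H:%M"),
              sum(x$missing)))
  invisible(x)
}

#' @export
as.data.frame.rate_series <- function(x, ...) {
  data.frame(timestamp = rs_times(x), rate = x$values,
             missing = as.integer(x$missing))
}

#' @export
plot.rate_series <- function(x, ..., ylab = "rate", xlab = "time") {
  v <- x$values
  v[x$missing] <- NA
  plot(rs_times(x), v, type = "l", ylab = ylab, xlab = xlab, ...)
  invisible(x)
}
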