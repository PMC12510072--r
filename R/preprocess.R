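#' Filter event detections by estimated probability
#'
#' Keeps only detections whose estimated probability of being a true event
#' is at least \code{threshold} (default 0.99, the inclusion rule for
#' automated detections), preserving order.
#'
#' @param events an \code{\link{event_series}}.
#' @param threshold probability threshold in \[0, 1\].
#' @return filtered \code{\link{event_series}}.
#' @export
filter_detections <- function(events, threshold = 0.99) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  out <- events[events$probability >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert event times to daily counts
#'
#' Bins event timestamps into calendar days (half-open \[00:00, 24:00) UTC
#' bins) over \code{start_date .. end_date} inclusive; events outside the
#' range are dropped.
#'
#' @param events an \code{\link{event_series}}.
#' @param start_date,end_date Date (or coercible) range bounds,
#'   \code{start_date <= end_date}.
#' @return a daily \code{\link{rate_series}} of integer counts whose sum
#'   equals the number of in-range events.
#' @export
events_to_daily_counts <- function(events, start_date, end_date) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (start_date > end_date) stop("start_date must not exceed end_date")
  if (nrow(events) > 1 && any(diff(as.numeric(events$timestamp)) < 0))
    stop("event timestamps must be ordered")
  n <- as.integer(end_date - start_date) + 1L
  origin <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  day_idx <- floor(as.numeric(events$timestamp - origin, units = "days")) + 1
  day_idx <- day_idx[day_idx >= 1 & day_idx <= n]
  counts <- tabulate(day_idx, nbins = n)
  rate_series(origin, "day", counts, rep(FALSE, n))
}

#' Fill recording gaps by noisy linear interpolation
#'
#' Interior runs of missing samples are replaced by the straight line
#' between the flanking observed values plus zero-mean Gaussian noise whose
#' SD is estimated from the observed data as
#' \code{sd(diff(observed)) / sqrt(2)} (the innovation scale implied by
#' first differences). Filled values are clipped at 0. Leading/trailing
#' missing samples are trimmed, since interpolation needs two anchors.
#'
#' @param series a \code{\link{rate_series}} with gaps flagged in its mask.
#' @param seed integer seed (the fill is deterministic given the seed).
#' @param noise_sd optional override of the estimated noise SD (0 gives
#'   plain linear interpolation).
#' @return a gap-free \code{\link{rate_series}}; identical input when there
#'   is nothing to fill.
#' @export
fill_gaps <- function(series, seed = 1L, noise_sd = NULL) {
  miss <- series$missing | !is.finite(series$values)
  if (all(miss)) stop("cannot fill an all-missing series")
  keep <- range(which(!miss))
  if (keep[1] > 1 || keep[2] < length(miss)) {
    series$start <- series$start + (keep[1] - 1) * step_seconds(series)
    series$values <- series$values[keep[1]:keep[2]]
    miss <- miss[keep[1]:keep[2]]
  }
  if (!any(miss)) {
    series$missing <- miss
    return(series)
  }
  idx <- seq_along(series$values)
  obs <- which(!miss)
  if (length(obs) < 2) stop("need at least 2 observed points to interpolate")
  interp <- stats::approx(obs, series$values[obs], xout = idx[miss])$y
  sd_hat <- if (is.null(noise_sd))
    stats::sd(diff(series$values[obs])) / sqrt(2) else noise_sd
  if (!is.finite(sd_hat)) sd_hat <- 0
  set.seed(as.integer(seed))
  filled <- interp + stats::rnorm(sum(miss), 0, sd_hat)
  series$values[miss] <- pmax(filled, 0)
  series$missing <- rep(FALSE, length(series$values))
  series
}

#' Causal moving-average seizure rate
#'
#' Long-term seizure rate as a causal \code{window_days}-day moving average
#' of daily counts: the value at day \eqn{t} is the mean of days
#' \eqn{t - w + 1, \dots, t}. The first \eqn{w - 1} days are a warm-up in
#' which the average is taken over the days available so far; they are
#' flagged in the mask and excluded from model fitting.
#'
#' @param daily a gap-free daily \code{\link{rate_series}} (run
#'   \code{\link{fill_gaps}} first).
#' @param window_days window length in days (default 90).
#' @return a \code{smoothed_rate}: a daily \code{\link{rate_series}} in
#'   seizures/day whose mask flags the warm-up, with a \code{window_days}
#'   field.
#' @export
causal_moving_average <- function(daily, window_days = 90) {
  if (daily$step != "day") stop("causal_moving_average() needs a daily series")
  if (window_days < 1) stop("window_days must be >= 1")
  if (any(daily$missing)) stop("series has missing values; fill gaps first")
  n <- length(daily$values)
  if (n < window_days) stop("series shorter than the smoothing window")
  cs <- cumsum(daily$values)
  out <- numeric(n)
  w <- as.integer(window_days)
  head_idx <- seq_len(w - 1)
  if (w > 1) out[head_idx] <- cs[head_idx] / head_idx
  full <- w:n
  out[full] <- (cs[full] - c(0, cs)[full - w + 1]) / w
  res <- rate_series(daily$start, "day", out,
                     c(rep(TRUE, w - 1), rep(FALSE, n - w + 1)))
  res$window_days <- w
  class(res) <- c("smoothed_rate", class(res))
  res
}

#' @export
print.smoothed_rate <- function(x, ...) {
  cat(sprintf(
    "<smoothed_rate> %d days, %d-day causal window (%d warm-up days)\n",
    length(x$values), x$window_days, sum(x$missing)))
  invisible(x)
}

# Values of a smoothed series with the warm-up removed, plus their dates.
smoothed_body <- function(x) {
  keep <- !x$missing
  list(values = x$values[keep], dates = rs_dates(x)[keep])
}
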