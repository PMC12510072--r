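# Shared fixtures, built in code at test time.

utc <- function(x) as.POSIXct(x, tz = "UTC")

# Daily rate series from a numeric vector.
daily_series <- function(values, start = "2020-01-01", missing = NULL) {
  rate_series(utc(paste(start, "00:00:00")), "day", values, missing)
}

# Hourly series of a pure sinusoid: amp * cos(2 pi t / period_days + phase)
# + offset, n_days long.
hourly_cosine <- function(period_days, n_days, amp = 1, phase = 0,
                          offset = 10) {
  t <- (seq_len(n_days * 24) - 1) / 24
  rate_series(utc("2020-01-01 00:00:00"), "hour",
              offset + amp * cos(2 * pi * t / period_days + phase))
}

# Event series at given day offsets (fractional days from a start date).
events_at <- function(day_offsets, start = "2020-01-01", ...) {
  event_series(utc(paste(start, "00:00:00")) + day_offsets * 86400, ...)
}

# Brute-force Kruskal-Wallis H with tie correction, from first principles
# (midranks by sorting, rank-sum formula), independent of stats::kruskal.test.
bf_kruskal_H <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  # midranks without rank(): count smaller + half the ties
  r <- vapply(seq_len(n), function(i)
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2, numeric(1))
  sizes <- vapply(groups, length, integer(1))
  idx <- rep(seq_along(groups), sizes)
  rs <- vapply(seq_along(groups), function(g) sum(r[idx == g]), numeric(1))
  H <- 12 / (n * (n + 1)) * sum(rs^2 / sizes) - 3 * (n + 1)
  tie_counts <- table(x)
  H / (1 - sum(tie_counts^3 - tie_counts) / (n^3 - n))
}

# Exact two-sided rank-sum p-value by enumerating all assignments of the
# pooled sample to the first group (tie-free data only).
bf_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n, n1)
  w_all <- apply(combs, 2, function(id) sum(r[id])) - n1 * (n1 + 1) / 2
  m <- n1 * (length(y))
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  if (w_obs > m / 2) min(1, 2 * p_ge) else min(1, 2 * p_le)
}

# One-scale-step period match on the default 24-per-octave grid.
within_scale_step <- function(found, truth, per_octave = 24) {
  any(abs(log2(found / truth)) <= 1 / per_octave + 1e-9)
}
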