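#' Candidate multidien periods
#'
#' Logarithmic period grid for cycle scanning: \code{per_octave} periods per
#' octave between \code{min_period} and \code{max_period} days.
#'
#' @param min_period,max_period period range in days (default 1--45).
#' @param per_octave scale-grid density (default 24).
#' @return numeric vector of periods (days), increasing.
#' @export
cycle_periods <- function(min_period = 1, max_period = 45, per_octave = 24) {
  if (min_period < 1 || max_period > 45 || min_period >= max_period)
    stop("periods must satisfy 1 <= min_period < max_period <= 45")
  p <- 2^seq(log2(min_period), log2(max_period), by = 1 / per_octave)
  if (p[length(p)] < max_period) p <- c(p, max_period)
  p
}

# Morlet mother-wavelet constants (centre frequency omega0 = 6).
MORLET_OMEGA0 <- 6
morlet_fourier_factor <- function(omega0 = MORLET_OMEGA0)
  4 * pi / (omega0 + sqrt(2 + omega0^2))

# Angular frequencies of an N-point DFT at sampling step dt.
dft_omega <- function(n, dt) {
  k <- seq_len(n) - 1
  k[k > n / 2] <- k[k > n / 2] - n
  2 * pi * k / (n * dt)
}

# Frequency-domain Morlet daughters: S x N matrix, row s = sqrt(2 pi s / dt)
# * pi^{-1/4} * exp(-(s w - w0)^2 / 2) on w > 0 (analytic wavelet).
morlet_daughters <- function(scales, omega, dt) {
  pos <- omega > 0
  out <- matrix(0, length(scales), length(omega))
  for (i in seq_along(scales)) {
    s <- scales[i]
    out[i, pos] <- sqrt(2 * pi * s / dt) * pi^(-0.25) *
      exp(-((s * omega[pos] - MORLET_OMEGA0)^2) / 2)
  }
  out
}

#' Continuous Morlet wavelet transform
#'
#' FFT-based continuous wavelet transform with the complex Morlet mother
#' wavelet (centre frequency \eqn{\omega_0 = 6}); scales are mapped from the
#' requested periods by the Morlet Fourier factor
#' \eqn{T = s \cdot 4\pi / (\omega_0 + \sqrt{2 + \omega_0^2})}. The
#' cone of influence excludes samples closer to either series edge than the
#' e-folding time \eqn{\sqrt{2} s}; the per-period global power averages
#' squared coefficient moduli over non-excluded samples only.
#'
#' @param series a gap-free \code{\link{rate_series}} (hourly or daily).
#' @param periods candidate periods in days (default
#'   \code{\link{cycle_periods}()}).
#' @param keep_coefficients keep the complex coefficient matrix (needed by
#'   \code{\link{extract_phase}} via the spectrum; default FALSE to save
#'   memory).
#' @return An object of class \code{wavelet_spectrum}: \code{periods},
#'   \code{scales}, \code{power} (period x time), \code{coi_excluded}
#'   (logical, period x time), \code{global_power}, \code{dt} (days),
#'   \code{times}.
#' @export
morlet_cwt <- function(series, periods = cycle_periods(),
                       keep_coefficients = FALSE) {
  if (any(series$missing | !is.finite(series$values)))
    stop("series has gaps; fill them before the wavelet transform")
  dt <- step_seconds(series) / 86400
  x <- series$values - mean(series$values)
  n <- length(x)
  if (n * dt < 2 * max(periods))
    stop("series shorter than twice the longest candidate period")
  scales <- periods / morlet_fourier_factor()
  omega <- dft_omega(n, dt)
  daughters <- morlet_daughters(scales, omega, dt)
  xh <- stats::fft(x)
  spec <- daughters * matrix(xh, length(scales), n, byrow = TRUE)
  W <- t(stats::mvfft(t(spec), inverse = TRUE)) / n
  power <- Mod(W)^2
  edge_dist <- pmin(seq_len(n) - 1, n - seq_len(n)) * dt
  coi <- outer(sqrt(2) * scales, edge_dist, ">")
  gp <- vapply(seq_along(scales), function(i) {
    ok <- !coi[i, ]
    if (!any(ok)) NA_real_ else mean(power[i, ok])
  }, numeric(1))
  out <- list(periods = periods, scales = scales, power = power,
              coi_excluded = coi, global_power = gp, dt = dt,
              times = rs_times(series))
  if (keep_coefficients) out$coefficients <- W
  structure(out, class = "wavelet_spectrum")
}

#' @export
print.wavelet_spectrum <- function(x, ...) {
  cat(sprintf(
    "<wavelet_spectrum> %d periods in [%.2f, %.1f] d x %d samples (dt = %.4f d)\n",
    length(x$periods), min(x$periods), max(x$periods), ncol(x$power), x$dt))
  ok <- is.finite(x$global_power)
  if (any(ok))
    cat(sprintf("  global-power peak at %.2f d\n",
                x$periods[ok][which.max(x$global_power[ok])]))
  invisible(x)
}

#' Permutation significance of multidien cycles
#'
#' Tests each candidate period's global wavelet power against a null built
#' from \code{n_perm} random shufflings of the series values (shuffling
#' destroys all temporal structure while keeping the marginal distribution).
#' Per-period p-values \eqn{p = (1 + \#\{null \ge obs\}) / (n_{perm} + 1)}
#' are corrected by Benjamini--Hochberg at \eqn{q = 1 - fdr\_level}
#' (0.05 when \code{fdr_level = 0.95}); contiguous significant periods are
#' collapsed to their local power maximum.
#'
#' The null global power of each shuffle is evaluated in closed spectral
#' form (by Parseval's identity the time-averaged squared coefficient
#' modulus equals \eqn{\sum_k |\hat x_k|^2 |\hat\psi(s\omega_k)|^2}), so
#' each permutation costs one FFT plus a matrix product; for an exchangeable
#' shuffled series this time average has the same expectation as the
#' cone-of-influence-restricted average used for the observed statistic.
#'
#' @param series a gap-free \code{\link{rate_series}}.
#' @param periods candidate periods in days.
#' @param n_perm number of permutations (>= 200).
#' @param fdr_level the paper-style FDR level; discoveries are controlled at
#'   \code{q = 1 - fdr_level}.
#' @param seed integer seed for the shuffles.
#' @param collapse collapse contiguous significant periods to local maxima
#'   (default TRUE).
#' @return An object of class \code{cycle_detection}: \code{periods},
#'   \code{global_power}, \code{p}, \code{p_adj}, \code{significant}
#'   (logical per period), \code{significant_periods} (after collapsing),
#'   \code{q}, \code{n_perm}.
#' @export
permutation_significance <- function(series, periods = cycle_periods(),
                                     n_perm = 500, fdr_level = 0.95,
                                     seed = 1L, collapse = TRUE) {
  if (n_perm < 200) stop("n_perm must be >= 200")
  q <- 1 - fdr_level
  if (q <= 0 || q >= 1) stop("fdr_level must lie in (0, 1)")
  spec <- morlet_cwt(series, periods)
  obs <- spec$global_power
  dt <- spec$dt
  x <- series$values - mean(series$values)
  n <- length(x)
  daughters2 <- morlet_daughters(spec$scales, dft_omega(n, dt), dt)^2
  set.seed(as.integer(seed))
  exceed <- integer(length(periods))
  for (i in seq_len(n_perm)) {
    ph <- Mod(stats::fft(sample(x)))^2 / n^2
    null_gp <- as.numeric(daughters2 %*% ph)
    exceed <- exceed + (null_gp >= obs)
  }
  p <- (1 + exceed) / (n_perm + 1)
  p[!is.finite(obs)] <- NA_real_
  p_adj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  p_adj[ok] <- stats::p.adjust(p[ok], method = "BH")
  sig <- !is.na(p_adj) & p_adj <= q
  sig_periods <- periods[sig]
  if (collapse && any(sig)) {
    runs <- rle(sig)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    sig_periods <- vapply(which(runs$values), function(r) {
      idx <- starts[r]:ends[r]
      periods[idx][which.max(obs[idx])]
    }, numeric(1))
  }
  structure(list(periods = periods, global_power = obs, p = p,
                 p_adj = p_adj, significant = sig,
                 significant_periods = sig_periods, q = q, n_perm = n_perm,
                 seed = as.integer(seed)),
            class = "cycle_detection")
}

#' @export
print.cycle_detection <- function(x, ...) {
  cat(sprintf("<cycle_detection> %d candidate periods, q = %.3g, %d permutations\n",
              length(x$periods), x$q, x$n_perm))
  if (length(x$significant_periods))
    cat("  significant periods (d):",
        paste(sprintf("%.2f", x$significant_periods), collapse = ", "), "\n")
  else cat("  no significant periods\n")
  invisible(x)
}

#' Instantaneous cycle phase at one period
#'
#' Phase of the complex Morlet coefficient at the scale corresponding to
#' \code{period}, per sample, in \eqn{(-\pi, \pi]}. On a pure cosine of the
#' same period the phase is 0 at the cosine peak and advances by
#' \eqn{2\pi / T} per day.
#'
#' @param series a gap-free \code{\link{rate_series}}.
#' @param period cycle period in days.
#' @return numeric vector of phases (radians), one per sample.
#' @export
extract_phase <- function(series, period) {
  if (any(series$missing | !is.finite(series$values)))
    stop("series has gaps; fill them before phase extraction")
  dt <- step_seconds(series) / 86400
  x <- series$values - mean(series$values)
  n <- length(x)
  s <- period / morlet_fourier_factor()
  omega <- dft_omega(n, dt)
  daughter <- as.numeric(morlet_daughters(s, omega, dt))
  W <- stats::fft(stats::fft(x) * daughter, inverse = TRUE) / n
  Arg(W)
}

# Reduce hourly per-sample phases to one value per day (the 12:00 sample,
# the midpoint of the day bin); daily input is returned as-is.
phase_to_daily <- function(phase, step = c("hour", "day")) {
  step <- match.arg(step)
  if (step == "day") return(phase)
  n_days <- length(phase) %/% 24L
  phase[(seq_len(n_days) - 1L) * 24L + 13L]
}

wrap_phase <- function(x) {
  w <- x %% (2 * pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  w
}

#' Sine/cosine phase regressors
#'
#' Builds the exogenous regressor matrix from per-period daily phases:
#' columns ordered \code{(sin, cos)} per period, so each row satisfies
#' \eqn{\sin^2\phi + \cos^2\phi = 1} per period.
#'
#' @param phases numeric matrix (day x period) of phases in radians, or a
#'   vector for a single period; column names (or \code{periods}) label the
#'   output columns.
#' @param periods optional period labels (days).
#' @return numeric matrix (day x 2 * n_periods) with columns
#'   \code{sin_<T>}, \code{cos_<T>}.
#' @export
build_phase_regressors <- function(phases, periods = NULL) {
  phases <- as.matrix(phases)
  k <- ncol(phases)
  if (is.null(periods)) {
    periods <- colnames(phases)
    if (is.null(periods)) periods <- as.character(seq_len(k))
  } else periods <- format(periods, trim = TRUE, digits = 4)
  out <- matrix(0, nrow(phases), 2L * k)
  cn <- character(2L * k)
  for (j in seq_len(k)) {
    out[, 2L * j - 1L] <- sin(phases[, j])
    out[, 2L * j] <- cos(phases[, j])
    cn[2L * j - 1L] <- paste0("sin_", periods[j])
    cn[2L * j] <- paste0("cos_", periods[j])
  }
  colnames(out) <- cn
  out
}

#' Project cycle phases forward
#'
#' Extrapolates a cycle's phase at constant angular velocity
#' \eqn{2\pi / T} per day from the last observed phase, wrapped to
#' \eqn{(-\pi, \pi]}.
#'
#' @param last_phase phase (radians) at the last observed day.
#' @param period cycle period in days.
#' @param horizon_days number of days ahead (0 returns the last phase).
#' @return numeric vector of projected phases for days
#'   \code{1..horizon_days} ahead (or \code{last_phase} when
#'   \code{horizon_days = 0}).
#' @export
project_phases <- function(last_phase, period, horizon_days) {
  if (horizon_days == 0) return(wrap_phase(last_phase))
  wrap_phase(last_phase + 2 * pi * seq_len(horizon_days) / period)
}

#' Detect significant cycles and build their regressors
#'
#' End-to-end cycle stage: permutation-test the candidate periods on
#' \code{series} (typically the training-span IED rate, avoiding test-set
#' leakage in period selection), then extract daily phases for the
#' significant periods from \code{phase_series} (default the same series;
#' pass the full recording when projections are needed outside the training
#' span) and assemble the sin/cos regressor matrix.
#'
#' @inheritParams permutation_significance
#' @param phase_series series used for phase extraction (defaults to
#'   \code{series}).
#' @return An object of class \code{cycle_set}: \code{significant_periods},
#'   \code{phase} (day x period matrix), \code{regressors}
#'   (day x 2 * n_periods), \code{dates}, \code{fdr_level},
#'   \code{detection} (the underlying \code{cycle_detection}).
#' @export
detect_cycles <- function(series, periods = cycle_periods(), n_perm = 500,
                          fdr_level = 0.95, seed = 1L,
                          phase_series = series) {
  det <- permutation_significance(series, periods, n_perm = n_perm,
                                  fdr_level = fdr_level, seed = seed)
  sig <- det$significant_periods
  n_days <- length(phase_series$values)
  if (phase_series$step == "hour") n_days <- n_days %/% 24L
  dates <- as.Date(phase_series$start) + seq_len(n_days) - 1
  if (!length(sig)) {
    phase <- matrix(numeric(0), n_days, 0)
    reg <- matrix(numeric(0), n_days, 0)
  } else {
    phase <- vapply(sig, function(T)
      phase_to_daily(extract_phase(phase_series, T), phase_series$step),
      numeric(n_days))
    colnames(phase) <- format(sig, trim = TRUE, digits = 4)
    reg <- build_phase_regressors(phase, periods = sig)
  }
  structure(list(significant_periods = sig, phase = phase, regressors = reg,
                 dates = dates, fdr_level = fdr_level, detection = det),
            class = "cycle_set")
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf("<cycle_set> %d significant period(s)",
              length(x$significant_periods)))
  if (length(x$significant_periods))
    cat(":", paste(sprintf("%.2f d", x$significant_periods), collapse = ", "))
  cat(sprintf("; %d days of phase regressors\n", nrow(x$regressors)))
  invisible(x)
}

# Future regressor rows for days origin+1 .. origin+h, by constant angular
# extrapolation from the phases at origin_idx.
future_regressors <- function(cycles, origin_idx, horizon) {
  k <- length(cycles$significant_periods)
  if (!k) return(matrix(numeric(0), horizon, 0))
  ph <- vapply(seq_len(k), function(j)
    project_phases(cycles$phase[origin_idx, j],
                   cycles$significant_periods[j], horizon),
    numeric(horizon))
  ph <- matrix(ph, nrow = horizon)
  reg <- build_phase_regressors(ph, periods = cycles$significant_periods)
  colnames(reg) <- colnames(cycles$regressors)
  reg
}
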