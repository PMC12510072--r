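#' Virtual-participant simulation configuration
#'
#' Defines the generative model for a virtual participant: daily seizure
#' intensity modulated by multidien (1--45 day) cycles, an hourly IED rate
#' phase-locked to the same cycles, an optional multiplicative drug effect
#' (with an optional short-lived titration transient), recording gaps, and
#' diary under-reporting by independent thinning.
#'
#' Defaults emulate a three-year implanted-EEG recording: ~2.8 seizures/day
#' baseline (so roughly 3100 detected seizures over the span), two multidien
#' cycles (20 d and 5 d), a drug change at day 300 whose chronic effect is a
#' multiplicative factor on intensity, a 45-day titration dip, two extended
#' recording gaps, and a diary capturing ~37.4% of detected events.
#'
#' @param n_days length of the recording in days.
#' @param baseline_rate expected seizures/day before modulation (> 0).
#' @param cycles list of numeric vectors \code{c(period, depth, phase)}:
#'   period in days within \[1, 45\], modulation depth in \[0, 1) with
#'   depths summing below 1, phase offset in radians.
#' @param ied_baseline expected IEDs/hour (> 0).
#' @param ied_cycle_gain per-cycle modulation depth of the IED rate
#'   (recycled to \code{length(cycles)}; gains must sum below 1).
#' @param ied_noise_sd SD of additive Gaussian noise on the hourly IED rate
#'   (truncated at 0).
#' @param drug_change_day day index (0-based) of the regimen change, or NULL.
#' @param drug_effect multiplicative factor on intensity from
#'   \code{drug_change_day} onward (1.0 = inert drug; must be > 0).
#' @param drug_transient NULL or \code{list(duration, factor)}: an extra
#'   multiplicative factor applied for the first \code{duration} days after
#'   the change (titration dip that fades with tolerance).
#' @param gaps list of numeric vectors \code{c(start_day, length_days)};
#'   non-overlapping, inside \[0, n_days).
#' @param diary_report_prob probability that a detected event is also
#'   diary-reported.
#' @param start_date calendar date of day 0.
#' @param seed integer seed used by \code{simulate_participant}.
#'
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_days = 1100,
                       baseline_rate = 2.8,
                       cycles = list(c(period = 20, depth = 0.3, phase = 0),
                                     c(period = 5, depth = 0.15,
                                       phase = pi / 3)),
                       ied_baseline = 40,
                       ied_cycle_gain = c(0.3, 0.15),
                       ied_noise_sd = 8,
                       drug_change_day = 300,
                       drug_effect = 1.0,
                       drug_transient = list(duration = 45, factor = 0.6),
                       gaps = list(c(start = 330, length = 30),
                                   c(start = 700, length = 21)),
                       diary_report_prob = 0.3744,
                       start_date = "2020-01-01",
                       seed = 1L) {
  cfg <- list(n_days = as.integer(n_days), baseline_rate = baseline_rate,
              cycles = cycles, ied_baseline = ied_baseline,
              ied_cycle_gain = rep_len(ied_cycle_gain,
                                       length.out = length(cycles)),
              ied_noise_sd = ied_noise_sd,
              drug_change_day = drug_change_day, drug_effect = drug_effect,
              drug_transient = drug_transient, gaps = gaps,
              diary_report_prob = diary_report_prob,
              start_date = as.Date(start_date), seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_days >= 1, cfg$baseline_rate > 0, cfg$ied_baseline > 0,
            cfg$ied_noise_sd >= 0)
  if (cfg$diary_report_prob < 0 || cfg$diary_report_prob > 1)
    stop("diary_report_prob must lie in [0, 1]")
  depths <- 0
  for (cy in cfg$cycles) {
    cy <- cycle_triple(cy)
    if (cy[["period"]] < 1 || cy[["period"]] > 45)
      stop("cycle periods must lie in [1, 45] days")
    if (cy[["depth"]] < 0 || cy[["depth"]] >= 1)
      stop("cycle depths must lie in [0, 1)")
    depths <- depths + cy[["depth"]]
  }
  if (depths >= 1)
    stop("cycle modulation depths must sum below 1 (intensity positivity)")
  if (length(cfg$cycles) && sum(abs(cfg$ied_cycle_gain)) >= 1)
    stop("IED cycle gains must sum below 1")
  if (!is.null(cfg$drug_change_day)) {
    if (cfg$drug_change_day < 0 || cfg$drug_change_day >= cfg$n_days)
      stop("drug_change_day must lie in [0, n_days)")
    if (cfg$drug_effect <= 0) stop("drug_effect must be > 0")
    if (!is.null(cfg$drug_transient) &&
        (cfg$drug_transient$factor <= 0 || cfg$drug_transient$duration < 0))
      stop("drug_transient factor must be > 0 and duration >= 0")
  }
  if (length(cfg$gaps)) {
    iv <- t(vapply(cfg$gaps, function(g) c(g[[1]], g[[1]] + g[[2]]),
                   numeric(2)))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[, 1] < 0) || any(iv[, 2] > cfg$n_days))
      stop("gaps must lie within [0, n_days)")
    if (nrow(iv) > 1 && any(iv[-1, 1] < iv[-nrow(iv), 2]))
      stop("gaps must not overlap")
  }
  invisible(cfg)
}

cycle_triple <- function(cy) {
  cy <- as.numeric(cy)
  if (length(cy) < 2) stop("each cycle needs at least (period, depth)")
  if (length(cy) == 2) cy <- c(cy, 0)
  names(cy) <- c("period", "depth", "phase")
  cy
}

drug_factor <- function(cfg, t) {
  f <- rep(1, length(t))
  if (!is.null(cfg$drug_change_day)) {
    post <- t >= cfg$drug_change_day
    f[post] <- cfg$drug_effect
    if (!is.null(cfg$drug_transient)) {
      tr <- post & t < cfg$drug_change_day + cfg$drug_transient$duration
      f[tr] <- f[tr] * cfg$drug_transient$factor
    }
  }
  f
}

#' Daily seizure intensity of a virtual participant
#'
#' Evaluates the inhomogeneous Poisson intensity
#' \deqn{\lambda(t) = r_0 \, (1 + \sum_k d_k \cos(2\pi t / T_k + \phi_k))
#'   \cdot f_{drug}(t)}
#' at integer days \eqn{t = 0, \dots, n\_days - 1}, where \eqn{f_{drug}}
#' is the multiplicative regimen factor (chronic effect times any titration
#' transient).
#'
#' @param config a \code{\link{sim_config}}.
#' @return numeric vector of length \code{n_days}, all values > 0.
#' @export
simulate_intensity <- function(config) {
  validate_sim_config(config)
  t <- seq_len(config$n_days) - 1
  mod <- rep(1, config$n_days)
  for (cy in config$cycles) {
    cy <- cycle_triple(cy)
    mod <- mod + cy[["depth"]] *
      cos(2 * pi * t / cy[["period"]] + cy[["phase"]])
  }
  lambda <- config$baseline_rate * mod * drug_factor(config, t)
  if (any(lambda <= 0))
    stop("configuration yields non-positive intensity")
  lambda
}

#' Draw seizure events from a daily intensity
#'
#' Inhomogeneous Poisson sampling: the event count of day \eqn{t} is
#' Poisson(\eqn{\lambda(t)}) and event times are uniform within the day.
#'
#' @param intensity daily intensity vector (seizures/day), all positive.
#' @param seed integer seed (draws are reproducible).
#' @param start_date calendar date of day 0.
#' @return an \code{\link{event_series}} (probability 1, unreported).
#' @export
simulate_events <- function(intensity, seed, start_date = "2020-01-01") {
  if (length(intensity) && any(intensity <= 0))
    stop("intensity must be positive")
  set.seed(as.integer(seed))
  origin <- as.POSIXct(paste(as.Date(start_date), "00:00:00"), tz = "UTC")
  counts <- stats::rpois(length(intensity), intensity)
  offs <- unlist(lapply(seq_along(counts), function(d) {
    if (counts[d] == 0) return(numeric(0))
    (d - 1) * 86400 + sort(stats::runif(counts[d], 0, 86400))
  }), use.names = FALSE)
  if (is.null(offs)) offs <- numeric(0)
  event_series(origin + offs)
}

#' Simulate the hourly IED rate series
#'
#' Hourly interictal-discharge rate sharing the cycle phases of the seizure
#' intensity: \eqn{r(t) = r_{IED} (1 + \sum_k g_k \cos(2\pi t / T_k +
#' \phi_k)) + \epsilon_t}, with Gaussian noise truncated at 0 and samples in
#' configured recording gaps marked missing.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed integer seed.
#' @return an hourly \code{\link{rate_series}} of length \code{24 * n_days}.
#' @export
simulate_ied_rates <- function(config, seed) {
  validate_sim_config(config)
  set.seed(as.integer(seed))
  n <- config$n_days * 24L
  t_days <- (seq_len(n) - 1) / 24
  r <- rep(1, n)
  gains <- config$ied_cycle_gain
  for (i in seq_along(config$cycles)) {
    cy <- cycle_triple(config$cycles[[i]])
    r <- r + gains[i] * cos(2 * pi * t_days / cy[["period"]] + cy[["phase"]])
  }
  vals <- config$ied_baseline * r
  if (config$ied_noise_sd > 0)
    vals <- vals + stats::rnorm(n, 0, config$ied_noise_sd)
  vals <- pmax(vals, 0)
  miss <- rep(FALSE, n)
  for (g in config$gaps) {
    h0 <- as.integer(g[[1]]) * 24L
    miss[(h0 + 1L):(h0 + as.integer(g[[2]]) * 24L)] <- TRUE
  }
  vals[miss] <- NA_real_
  rate_series(as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC"),
              "hour", vals, miss)
}

#' Thin detected events into a diary
#'
#' Emulates diary under-reporting: each detected event is recorded
#' independently with probability \code{p}.
#'
#' @param events an \code{\link{event_series}} of detections.
#' @param p reporting probability in \[0, 1\].
#' @param seed integer seed.
#' @return an \code{\link{event_series}} that is a subset of \code{events},
#'   with \code{reported = TRUE}.
#' @export
simulate_diary <- function(events, p, seed) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  set.seed(as.integer(seed))
  keep <- stats::runif(nrow(events)) < p
  out <- events[keep, , drop = FALSE]
  out$reported <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Simulate a complete virtual participant
#'
#' Runs intensity, event, IED and diary simulation under one seed and
#' assembles the regimen annotation (pre/post drug change).
#'
#' @param config a \code{\link{sim_config}}.
#' @return A list of class \code{virtual_participant} with elements
#'   \code{seizure_events}, \code{ied_rates}, \code{diary_events},
#'   \code{regimen_intervals} (data frame label/start/end) and \code{truth}
#'   (the generating config).
#' @export
simulate_participant <- function(config = sim_config()) {
  validate_sim_config(config)
  lambda <- simulate_intensity(config)
  events <- simulate_events(lambda, seed = config$seed,
                            start_date = config$start_date)
  ied <- simulate_ied_rates(config, seed = config$seed + 1L)
  diary <- simulate_diary(events, config$diary_report_prob,
                          seed = config$seed + 2L)
  d0 <- config$start_date
  if (is.null(config$drug_change_day)) {
    reg <- data.frame(label = "regimen-1", start = d0,
                      end = d0 + config$n_days - 1)
  } else {
    chg <- d0 + config$drug_change_day
    reg <- data.frame(label = c("pre-drug", "post-drug"),
                      start = c(d0, chg),
                      end = c(chg - 1, d0 + config$n_days - 1))
  }
  structure(list(seizure_events = events, ied_rates = ied,
                 diary_events = diary, regimen_intervals = reg,
                 truth = config),
            class = "virtual_participant")
}

#' @export
print.virtual_participant <- function(x, ...) {
  cat(sprintf(
    "<virtual_participant> %d days; %d seizures detected, %d diary-reported\n",
    x$truth$n_days, nrow(x$seizure_events), nrow(x$diary_events)))
  invisible(x)
}
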