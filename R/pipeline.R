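#' Subset a rate series by date range
#'
#' @param x a \code{\link{rate_series}}.
#' @param start_date,end_date inclusive Date bounds.
#' @return a \code{\link{rate_series}} covering the requested days.
#' @export
rs_window <- function(x, start_date, end_date) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  t0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(end_date + 1, "00:00:00"), tz = "UTC")
  tt <- rs_times(x)
  sel <- tt >= t0 & tt < t1
  if (!any(sel)) stop("window contains no samples")
  rate_series(tt[sel][1], x$step, x$values[sel], x$missing[sel])
}

#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end workflow with the
#' defaults used throughout: detection-probability threshold 0.99, 90-day
#' causal smoothing window, 1--45 d candidate periods with 500
#' permutations at FDR level 0.95, an ARIMAX(5,1,1) projection model with
#' 14-day horizon, a +/-3 SD monitoring band with 14-day persistence, and
#' 14-day performance blocks at alpha = 0.05.
#'
#' @param sim a \code{\link{sim_config}} describing the virtual
#'   participant (set \code{events_csv}/\code{ied_csv} instead to run on
#'   recorded inputs).
#' @param events_csv,ied_csv optional paths to input CSVs (used when
#'   \code{sim} is NULL).
#' @param threshold detection-probability threshold.
#' @param window smoothing window (days).
#' @param min_period,max_period,per_octave candidate-period grid.
#' @param n_perm permutations for cycle significance.
#' @param fdr_level FDR level (discoveries controlled at 1 - fdr_level).
#' @param order projection \code{\link{model_order}}.
#' @param horizon projection horizon (days).
#' @param k_sd monitoring band half-width (SDs).
#' @param persistence changepoint persistence (days).
#' @param block_len performance-block length (days).
#' @param alpha significance level.
#' @param n_surrogates surrogate replicates.
#' @param split optional \code{\link{dataset_split}}; derived from the
#'   simulation layout when NULL.
#' @param seed master seed for the stochastic stages.
#' @return a list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(sim = sim_config(), events_csv = NULL,
                            ied_csv = NULL, threshold = 0.99, window = 90,
                            min_period = 1, max_period = 45,
                            per_octave = 24, n_perm = 500,
                            fdr_level = 0.95,
                            order = model_order(5, 1, 1, use_exog = TRUE),
                            horizon = 14, k_sd = 3, persistence = 14,
                            block_len = 14, alpha = 0.05,
                            n_surrogates = 1, split = NULL, seed = 1L) {
  structure(list(sim = sim, events_csv = events_csv, ied_csv = ied_csv,
                 threshold = threshold, window = window,
                 min_period = min_period, max_period = max_period,
                 per_octave = per_octave, n_perm = n_perm,
                 fdr_level = fdr_level, order = order, horizon = horizon,
                 k_sd = k_sd, persistence = persistence,
                 block_len = block_len, alpha = alpha,
                 n_surrogates = n_surrogates, split = split,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Default segment layout for a simulated participant
#'
#' Derives a \code{\link{dataset_split}} from the simulation layout,
#' mirroring the study design: two ~3-month pre-drug test segments, one
#' early post-drug test segment, a 369-day post-drug training/validation
#' span, and one late post-drug test segment.
#'
#' @param config a \code{\link{sim_config}} with a drug change day.
#' @return a \code{\link{dataset_split}}.
#' @export
default_split <- function(config) {
  if (is.null(config$drug_change_day))
    stop("default_split() needs a drug change day")
  d0 <- config$start_date
  chg <- config$drug_change_day
  if (config$n_days < chg + 740 || chg < 300)
    stop("layout needs >= 300 pre-drug and >= 740 post-drug days")
  seg <- data.frame(
    label = c("pre-drug-1", "pre-drug-2", "post-drug-1", "post-drug-2"),
    start = d0 + c(chg - 180, chg - 90, chg + 100, chg + 650),
    end = d0 + c(chg - 91, chg - 1, chg + 189, chg + 739))
  dataset_split(d0 + chg + 190, d0 + chg + 558, seg)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("%s stage: %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the end-to-end analysis pipeline
#'
#' Composes the full workflow: simulate (or load) the participant data,
#' preprocess events and IED rates into the smoothed seizure rate, detect
#' significant multidien cycles on the training span, fit the projection
#' model, roll daily horizon-ahead projections, compare per-segment
#' performance (with a surrogate control), and monitor residuals against
#' the reference band. All artifacts are written as plain CSV/JSON under
#' \code{out_dir}; any stage failure aborts with the stage name.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir output directory (created if needed); NULL skips writing.
#' @return Invisibly, a list with the in-memory artifacts:
#'   \code{participant}, \code{smoothed}, \code{cycles}, \code{fit},
#'   \code{projections}, \code{report}, \code{surrogate}, \code{monitor},
#'   \code{split}, \code{concordance}.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  participant <- run_stage("simulate", {
    if (!is.null(config$sim)) {
      simulate_participant(config$sim)
    } else {
      if (is.null(config$events_csv))
        stop("need either a simulation config or input CSV paths")
      list(seizure_events = read_event_series(config$events_csv),
           ied_rates = if (!is.null(config$ied_csv))
             read_rate_series(config$ied_csv),
           diary_events = NULL, truth = NULL)
    }
  })
  split <- run_stage("split", {
    if (!is.null(config$split)) config$split
    else if (!is.null(config$sim)) default_split(config$sim)
    else stop("a dataset_split is required for non-simulated inputs")
  })
  prep <- run_stage("preprocess", {
    ev <- filter_detections(participant$seizure_events, config$threshold)
    if (!is.null(participant$ied_rates)) {
      dts <- rs_dates_span(participant$ied_rates)
      ied <- fill_gaps(participant$ied_rates, seed = config$seed + 10L)
    } else {
      dts <- as.Date(range(ev$timestamp))
      ied <- NULL
    }
    daily <- events_to_daily_counts(ev, dts[1], dts[2])
    smoothed <- causal_moving_average(daily, config$window)
    list(events = ev, daily = daily, ied = ied, smoothed = smoothed)
  })
  cycles <- run_stage("cycles", {
    if (is.null(prep$ied)) stop("no IED series available")
    train_ied <- rs_window(prep$ied, split$train_start, split$train_end)
    detect_cycles(train_ied,
                  periods = cycle_periods(config$min_period,
                                          config$max_period,
                                          config$per_octave),
                  n_perm = config$n_perm, fdr_level = config$fdr_level,
                  seed = config$seed + 20L, phase_series = prep$ied)
  })
  order <- config$order
  if (order$use_exog && !length(cycles$significant_periods)) {
    order <- model_order(order$p, order$d, order$q, use_exog = FALSE)
  }
  fit <- run_stage("fit",
                   fit_train(prep$smoothed, order, split, cycles))
  records <- run_stage("project",
                       rolling_projection(prep$smoothed, fit = fit,
                                          cycles = cycles,
                                          horizon = config$horizon))
  report <- run_stage("evaluate",
                      evaluate_performance(records, split,
                                           block_len = config$block_len,
                                           alpha = config$alpha))
  surrogate <- if (config$n_surrogates >= 1) run_stage("evaluate", {
    rep <- surrogate_control(prep$smoothed, order, split, cycles = cycles,
                             horizon = config$horizon,
                             n_shuffles = config$n_surrogates,
                             seed = config$seed + 30L,
                             block_len = config$block_len,
                             alpha = config$alpha)
    if (is.list(rep) && !inherits(rep, "evaluation_report")) rep[[1]] else rep
  })
  monitor <- run_stage("monitor", {
    ref <- records$residual[records$target_date >= split$train_start &
                              records$target_date <= split$train_end]
    monitor_residuals(records, ref, k_sd = config$k_sd,
                      persistence_days = config$persistence)
  })
  concordance <- if (!is.null(participant$diary_events) &&
                     nrow(prep$events) > 0)
    reporting_concordance(prep$events, participant$diary_events)
  else NA_real_
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_event_series(prep$events, file.path(out_dir, "events.csv"))
    if (!is.null(participant$diary_events))
      write_event_series(participant$diary_events,
                         file.path(out_dir, "diary.csv"))
    write_rate_series(prep$ied, file.path(out_dir, "ied_filled.csv"))
    write_rate_series(prep$smoothed, file.path(out_dir, "smoothed.csv"))
    if (length(cycles$significant_periods)) {
      utils::write.csv(
        data.frame(date = format(cycles$dates),
                   round(cycles$regressors, 6)),
        file.path(out_dir, "cycles.csv"), row.names = FALSE, quote = FALSE)
    }
    write_projections(records, file.path(out_dir, "projections.csv"))
    write_report(report, file.path(out_dir, "report.json"),
                 surrogate = surrogate,
                 extra = list(
                   diary_concordance_pct = concordance,
                   significant_periods_days = cycles$significant_periods,
                   changepoints = format(monitor$changepoints),
                   monitor_band = as.list(monitor$band),
                   model = format(order), horizon = config$horizon,
                   seed = config$seed))
    writeLines(c(
      sprintf("szproject %s | R %s.%s",
              as.character(utils::packageVersion("szproject")),
              R.version$major, R.version$minor),
      sprintf("seed: %d", config$seed),
      sprintf("model: %s, horizon %d d", format(order), config$horizon),
      sprintf("threshold %.2f | window %d d | periods [%g, %g] d | n_perm %d | q %.3g",
              config$threshold, config$window, config$min_period,
              config$max_period, config$n_perm, 1 - config$fdr_level),
      sprintf("band +/- %g SD, persistence %d d | blocks %d d | alpha %.2f",
              config$k_sd, config$persistence, config$block_len,
              config$alpha)),
      file.path(out_dir, "run.log"))
  }
  invisible(list(participant = participant, smoothed = prep$smoothed,
                 daily = prep$daily, ied = prep$ied, cycles = cycles,
                 fit = fit, projections = records, report = report,
                 surrogate = surrogate, monitor = monitor, split = split,
                 concordance = concordance))
}

# First and last calendar dates covered by a rate series.
rs_dates_span <- function(x) {
  tt <- rs_times(x)
  c(as.Date(tt[1]), as.Date(tt[length(tt)]))
}
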