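#' Train/validation and test segment layout
#'
#' Labelled, non-overlapping date intervals: one training/validation span
#' and several test segments (typically two pre-drug and two post-drug,
#' each 3--4 months long).
#'
#' @param train_start,train_end Date bounds of the training/validation span.
#' @param segments data frame with columns \code{label}, \code{start},
#'   \code{end} (Dates); labels must be unique and intervals disjoint.
#' @return an object of class \code{dataset_split}.
#' @export
dataset_split <- function(train_start, train_end, segments) {
  train_start <- as.Date(train_start); train_end <- as.Date(train_end)
  segments$start <- as.Date(segments$start)
  segments$end <- as.Date(segments$end)
  stopifnot(train_start <= train_end, all(segments$start <= segments$end))
  if (anyDuplicated(segments$label)) stop("segment labels must be unique")
  iv <- segments[order(segments$start), ]
  if (nrow(iv) > 1 && any(iv$start[-1] <= iv$end[-nrow(iv)]))
    stop("segments must not overlap")
  structure(list(train_start = train_start, train_end = train_end,
                 segments = segments),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train/validation %s .. %s; %d test segments\n",
              format(x$train_start), format(x$train_end), nrow(x$segments)))
  for (i in seq_len(nrow(x$segments)))
    cat(sprintf("  %-14s %s .. %s\n", x$segments$label[i],
                format(x$segments$start[i]), format(x$segments$end[i])))
  invisible(x)
}

#' Group projection residuals by segment
#'
#' Assigns each projection record to the segment containing its target
#' date (segments are disjoint, so no record lands in two groups); the
#' training/validation span is included as group \code{"train"} when
#' requested. Segments with no records are dropped with a warning.
#'
#' @param records an \code{sz_projections} data frame.
#' @param split a \code{\link{dataset_split}}.
#' @param include_train include the train/validation residuals as a group.
#' @return named list of residual vectors.
#' @export
segment_residuals <- function(records, split, include_train = TRUE) {
  seg <- split$segments
  labels <- seg$label
  starts <- seg$start
  ends <- seg$end
  if (include_train) {
    labels <- c("train", labels)
    starts <- c(split$train_start, starts)
    ends <- c(split$train_end, ends)
  }
  out <- list()
  for (i in seq_along(labels)) {
    sel <- records$target_date >= starts[i] & records$target_date <= ends[i]
    r <- records$residual[sel]
    r <- r[is.finite(r)]
    if (!length(r)) {
      warning(sprintf("segment '%s' contains no records; excluded", labels[i]))
      next
    }
    out[[labels[i]]] <- r
  }
  out
}

#' Per-block mean squared errors
#'
#' Splits a residual vector into consecutive non-overlapping blocks of
#' \code{block_len} values (dropping the incomplete tail) and returns each
#' block's mean squared residual. Daily h-step-ahead residuals from
#' overlapping origins share innovations over a range of about one horizon,
#' so horizon-length blocks give approximately exchangeable performance
#' samples for the rank tests.
#'
#' @param residuals numeric vector of residuals (in temporal order).
#' @param block_len block length in days (default 14, one horizon).
#' @return numeric vector of block MSEs.
#' @export
block_mse <- function(residuals, block_len = 14) {
  n_blocks <- length(residuals) %/% block_len
  if (n_blocks < 1) return(numeric(0))
  m <- matrix(residuals[seq_len(n_blocks * block_len)], nrow = block_len)
  colMeans(m^2)
}

#' Omnibus and post-hoc performance comparison
#'
#' Kruskal--Wallis rank test (with tie correction) across the groups,
#' followed by pairwise two-sided Wilcoxon rank-sum tests with Bonferroni
#' correction (multiplier = number of pairs).
#'
#' @param groups named list of >= 2 numeric vectors (each of length >= 2),
#'   typically per-block MSEs per segment.
#' @param alpha significance level recorded in the report (default 0.05).
#' @return An object of class \code{evaluation_report} with \code{kw_H},
#'   \code{kw_df}, \code{kw_p}, \code{posthoc} (symmetric matrix of
#'   Bonferroni-adjusted p-values), \code{posthoc_raw}, \code{alpha},
#'   \code{group_sizes}.
#' @export
omnibus_and_posthoc <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs at least 2 values")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  if (length(unique(unlist(groups))) == 1L) {
    # all pooled values tied: every rank is the midrank, H is 0 by definition
    kw <- list(statistic = c(H = 0),
               parameter = c(df = length(groups) - 1), p.value = 1)
  } else kw <- stats::kruskal.test(groups)
  k <- length(groups)
  raw <- matrix(NA_real_, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
    p <- suppressWarnings(
      stats::wilcox.test(groups[[i]], groups[[j]])$p.value)
    raw[i, j] <- raw[j, i] <- p
  }
  n_pairs <- k * (k - 1) / 2
  adj <- raw * n_pairs
  adj[!is.na(adj) & adj > 1] <- 1
  structure(list(kw_H = unname(kw$statistic), kw_df = unname(kw$parameter),
                 kw_p = kw$p.value, posthoc = adj, posthoc_raw = raw,
                 alpha = alpha,
                 group_sizes = vapply(groups, length, integer(1))),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> Kruskal-Wallis H = %.2f, df = %d, p = %.3g\n",
              x$kw_H, x$kw_df, x$kw_p))
  if (!is.null(x$per_segment_mse)) {
    cat("  per-segment MSE:\n")
    print(round(unlist(x$per_segment_mse), 4))
  }
  cat(sprintf("  post-hoc (Bonferroni-adjusted, alpha = %.2g):\n", x$alpha))
  print(round(x$posthoc, 4))
  invisible(x)
}

#' Segment-wise performance evaluation
#'
#' Computes the per-segment MSE of the rolling projections and the
#' Kruskal--Wallis / Wilcoxon--Bonferroni comparison of per-block MSEs
#' across segments.
#'
#' @param records an \code{sz_projections} data frame.
#' @param split a \code{\link{dataset_split}}.
#' @param block_len performance-block length in days (default 14).
#' @param alpha significance level (default 0.05).
#' @param include_train include the training span as a comparison group.
#' @return an \code{evaluation_report} with a \code{per_segment_mse} field.
#' @export
evaluate_performance <- function(records, split, block_len = 14,
                                 alpha = 0.05, include_train = TRUE) {
  groups <- segment_residuals(records, split, include_train = include_train)
  seg_mse <- lapply(groups, function(r) mean(r^2))
  blocks <- lapply(groups, block_mse, block_len = block_len)
  blocks <- blocks[vapply(blocks, length, integer(1)) >= 2]
  rep <- omnibus_and_posthoc(blocks, alpha = alpha)
  rep$per_segment_mse <- seg_mse
  rep$block_len <- block_len
  rep
}

#' Value-shuffled surrogate of a series
#'
#' Returns a copy of the series with its values randomly permuted (dates
#' and mask positions kept), destroying all temporal structure while
#' preserving the multiset of values.
#'
#' @param series a \code{\link{rate_series}} (or \code{smoothed_rate}).
#' @param seed integer seed.
#' @return series of the same class with shuffled values. For a
#'   \code{smoothed_rate} only the post-warm-up body is shuffled.
#' @export
surrogate_series <- function(series, seed = 1L) {
  set.seed(as.integer(seed))
  idx <- which(!series$missing)
  series$values[idx] <- sample(series$values[idx])
  series
}

#' Surrogate-data control
#'
#' Re-runs the projection and evaluation pipeline on value-shuffled copies
#' of the modelled series (train/validation/test splits kept), as a
#' negative control: with temporal structure destroyed the model should
#' show no systematic performance differences between segments.
#'
#' @param series the modelled \code{smoothed_rate}.
#' @param order a \code{\link{model_order}}.
#' @param split a \code{\link{dataset_split}}.
#' @param cycles optional \code{cycle_set} for exogenous orders.
#' @param horizon projection horizon (default 14).
#' @param n_shuffles number of surrogate replicates (default 1).
#' @param seed integer seed.
#' @param block_len,alpha passed to \code{\link{evaluate_performance}}.
#' @return a single \code{evaluation_report} (when \code{n_shuffles = 1})
#'   or a list of them.
#' @export
surrogate_control <- function(series, order, split, cycles = NULL,
                              horizon = 14, n_shuffles = 1, seed = 1L,
                              block_len = 14, alpha = 0.05) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  reports <- vector("list", n_shuffles)
  for (s in seq_len(n_shuffles)) {
    surr <- surrogate_series(series, seed = as.integer(seed) + s - 1L)
    fit <- fit_train(surr, order, split, cycles)
    rec <- rolling_projection(surr, fit = fit, cycles = cycles,
                              horizon = horizon)
    reports[[s]] <- evaluate_performance(rec, split, block_len = block_len,
                                         alpha = alpha)
  }
  if (n_shuffles == 1) reports[[1]] else reports
}

# Fit an order on the training/validation span of a daily series.
fit_train <- function(series, order, split, cycles = NULL) {
  body <- series_body(series)
  sel <- body$dates >= split$train_start & body$dates <= split$train_end
  if (!any(sel)) stop("training span contains no data")
  exog <- NULL
  if (order$use_exog) {
    if (is.null(cycles)) stop("exogenous order needs cycles")
    idx <- match(as.character(body$dates[sel]), as.character(cycles$dates))
    if (anyNA(idx)) stop("cycle regressors do not cover the training span")
    exog <- cycles$regressors[idx, , drop = FALSE]
  }
  fit_model(body$values[sel], order, exog = exog)
}

#' Residual control-band monitoring
#'
#' Compares projection residuals against the reference band
#' \eqn{\bar r \pm k \cdot s_r} formed from training/validation residuals.
#' A day is flagged when its residual falls outside the band; a changepoint
#' is declared at the first day of any run of at least
#' \code{persistence_days} consecutive days in one flag state following the
#' opposite (confirmed) state, so a sustained excursion yields one onset
#' changepoint and the return to normal another.
#'
#' @param records an \code{sz_projections} data frame (ordered by target
#'   date).
#' @param reference numeric vector of reference residuals (>= 30 values,
#'   non-degenerate).
#' @param k_sd band half-width in reference SDs (default 3).
#' @param persistence_days minimum run length for a state change (default
#'   14, one projection horizon).
#' @return An object of class \code{monitor_state}: \code{ref_mean},
#'   \code{ref_sd}, \code{band} (lower/upper), \code{flags} (logical per
#'   record), \code{dates}, \code{changepoints} (Dates), \code{k_sd},
#'   \code{persistence_days}.
#' @export
monitor_residuals <- function(records, reference, k_sd = 3,
                              persistence_days = 14) {
  reference <- reference[is.finite(reference)]
  if (length(reference) < 30)
    stop("need at least 30 reference residuals")
  m <- mean(reference)
  s <- stats::sd(reference)
  if (s == 0) stop("reference residual SD is zero")
  r <- records$residual
  flags <- abs(r - m) > k_sd * s
  flags[!is.finite(r)] <- FALSE
  cps <- as.Date(character(0))
  runs <- rle(flags)
  if (length(runs$lengths) > 1) {
    starts <- cumsum(c(1L, runs$lengths[-length(runs$lengths)]))
    confirmed <- runs$values[1]
    for (i in seq_along(runs$lengths)[-1]) {
      if (runs$values[i] != confirmed && runs$lengths[i] >= persistence_days) {
        cps <- c(cps, as.Date(records$target_date[starts[i]]))
        confirmed <- runs$values[i]
      }
    }
  }
  structure(list(ref_mean = m, ref_sd = s,
                 band = c(lower = m - k_sd * s, upper = m + k_sd * s),
                 flags = flags, dates = as.Date(records$target_date),
                 changepoints = cps, k_sd = k_sd,
                 persistence_days = persistence_days),
            class = "monitor_state")
}

#' @export
print.monitor_state <- function(x, ...) {
  cat(sprintf(
    "<monitor_state> band %.4g .. %.4g (+/- %g SD); %d/%d days flagged\n",
    x$band["lower"], x$band["upper"], x$k_sd, sum(x$flags), length(x$flags)))
  if (length(x$changepoints))
    cat("  changepoints:", paste(format(x$changepoints), collapse = ", "),
        "\n")
  else cat("  no changepoints\n")
  invisible(x)
}

#' @export
plot.monitor_state <- function(x, residuals = NULL, ...,
                               ylab = "projection residual") {
  if (is.null(residuals)) residuals <- rep(NA_real_, length(x$dates))
  plot(x$dates, residuals, type = "l", xlab = "date", ylab = ylab, ...)
  graphics::abline(h = c(x$band, x$ref_mean), lty = c(2, 2, 3),
                   col = "grey40")
  if (length(x$changepoints))
    graphics::abline(v = x$changepoints, col = "firebrick")
  invisible(x)
}

#' Diary reporting concordance
#'
#' Percentage of detected events that were also diary-reported,
#' rounded to two decimals.
#'
#' @param detected \code{\link{event_series}} of detections (non-empty).
#' @param reported \code{\link{event_series}} of diary events (a subset of
#'   the detections).
#' @return numeric percentage (e.g. 37.44).
#' @export
reporting_concordance <- function(detected, reported) {
  nd <- nrow(detected)
  if (nd == 0) stop("no detected events")
  nr <- nrow(reported)
  if (nr > nd) stop("reported events exceed detections")
  round(100 * nr / nd, 2)
}
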