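#' ARIMA(X) model order
#'
#' @param p autoregressive order (>= 0).
#' @param d differencing order (0, 1 or 2).
#' @param q moving-average order (>= 0).
#' @param use_exog include the sin/cos cycle-phase regressors.
#' @return an object of class \code{model_order}.
#' @export
model_order <- function(p, d = 0, q = 0, use_exog = FALSE) {
  p <- as.integer(p); d <- as.integer(d); q <- as.integer(q)
  if (p < 0 || q < 0 || !(d %in% 0:2)) stop("invalid ARIMA order")
  if (p + d + q < 1) stop("order must have p + d + q >= 1")
  structure(list(p = p, d = d, q = q, use_exog = isTRUE(use_exog)),
            class = "model_order")
}

#' @export
format.model_order <- function(x, ...)
  sprintf("%s(%d,%d,%d)", if (x$use_exog) "ARIMAX" else "ARIMA",
          x$p, x$d, x$q)

#' @export
print.model_order <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# Longest lag the model conditions on.
max_lag <- function(order) max(order$p + order$d, order$q)

# Numeric body of the modelled series: smoothed_rate drops its warm-up.
series_body <- function(series) {
  if (inherits(series, "smoothed_rate")) {
    b <- smoothed_body(series)
    list(values = b$values, dates = b$dates)
  } else if (inherits(series, "rate_series")) {
    if (series$step != "day") stop("modelling requires a daily series")
    if (any(series$missing)) stop("series has gaps; fill them first")
    list(values = series$values, dates = rs_dates(series))
  } else if (is.numeric(series)) {
    list(values = as.numeric(series), dates = seq_along(series))
  } else stop("unsupported series type")
}

#' Fit an ARIMA(X) model to the smoothed seizure rate
#'
#' Maximum-likelihood (CSS-ML, falling back to CSS) estimation via
#' \code{stats::arima}; exogenous sin/cos cycle-phase regressors enter as a
#' regression with ARIMA errors. A constant series is handled as a
#' degenerate fit (intercept = the constant, innovation variance 0), and
#' non-convergence yields a flagged (unconverged) result rather than an
#' error so that grid search can skip it.
#'
#' @param series a \code{smoothed_rate}, daily \code{\link{rate_series}} or
#'   numeric vector.
#' @param order a \code{\link{model_order}}.
#' @param exog regressor matrix aligned row-for-row with the modelled
#'   values (required when \code{order$use_exog}).
#' @param fixed optional vector of fixed coefficients passed to
#'   \code{stats::arima} (same layout as its \code{fixed} argument).
#' @return An object of class \code{sz_fit}.
#' @export
fit_model <- function(series, order, exog = NULL, fixed = NULL) {
  body <- series_body(series)
  x <- body$values
  n <- length(x)
  if (order$use_exog) {
    if (is.null(exog)) stop("order requests exogenous regressors; none given")
    exog <- as.matrix(exog)
    if (nrow(exog) != n) stop("exog rows must align with the series")
  } else exog <- NULL
  min_n <- order$p + order$d + order$q + 20L
  if (is.null(fixed) && n < min_n)
    stop(sprintf("series too short: need >= %d points for %s", min_n,
                 format(order)))
  template <- list(order = order, n = n, dates = body$dates, exog = exog,
                   x = x)
  if (stats::sd(x) < 1e-10 && is.null(fixed)) {
    return(structure(c(template, list(
      fit = NULL, coef = c(intercept = mean(x)), sigma2 = 0,
      residuals = rep(0, n), converged = TRUE, degenerate = TRUE)),
      class = "sz_fit"))
  }
  ord <- c(order$p, order$d, order$q)
  fit <- suppressWarnings(tryCatch(
    stats::arima(x, order = ord, xreg = exog,
                 include.mean = (order$d == 0), fixed = fixed,
                 transform.pars = is.null(fixed), method = "CSS-ML",
                 optim.control = list(maxit = 500)),
    error = function(e) tryCatch(
      stats::arima(x, order = ord, xreg = exog,
                   include.mean = (order$d == 0), fixed = fixed,
                   transform.pars = FALSE, method = "CSS"),
      error = function(e2) NULL)))
  if (is.null(fit)) {
    return(structure(c(template, list(
      fit = NULL, coef = NULL, sigma2 = NA_real_, residuals = NULL,
      converged = FALSE, degenerate = FALSE)), class = "sz_fit"))
  }
  structure(c(template, list(
    fit = fit, coef = stats::coef(fit), sigma2 = fit$sigma2,
    residuals = as.numeric(stats::residuals(fit)), converged = TRUE,
    degenerate = FALSE)), class = "sz_fit")
}

#' @export
print.sz_fit <- function(x, ...) {
  cat(sprintf("<sz_fit> %s on %d days", format(x$order), x$n))
  if (!x$converged) {
    cat(" [did not converge]\n")
    return(invisible(x))
  }
  cat(sprintf(", sigma^2 = %.4g\n", x$sigma2))
  if (length(x$coef)) print(round(x$coef, 4))
  invisible(x)
}

#' @export
coef.sz_fit <- function(object, ...) object$coef

#' @export
residuals.sz_fit <- function(object, ...) object$residuals

#' @export
summary.sz_fit <- function(object, ...) {
  out <- list(order = object$order, coef = object$coef,
              sigma2 = object$sigma2, converged = object$converged,
              n = object$n,
              se = if (!is.null(object$fit))
                sqrt(diag(object$fit$var.coef)) else NULL)
  class(out) <- "summary.sz_fit"
  out
}

#' @export
print.summary.sz_fit <- function(x, ...) {
  cat(format(x$order), "fit on", x$n, "days\n")
  if (!x$converged) {
    cat("did not converge\n")
    return(invisible(x))
  }
  tab <- cbind(estimate = x$coef)
  if (!is.null(x$se) && length(x$se) == length(x$coef))
    tab <- cbind(tab, s.e. = x$se)
  print(round(tab, 4))
  cat(sprintf("innovation variance: %.4g\n", x$sigma2))
  invisible(x)
}

#' @export
predict.sz_fit <- function(object, n.ahead = 14, newxreg = NULL, ...) {
  project(object, history = object$x, history_exog = object$exog,
          future_exog = newxreg, horizon = n.ahead)
}

#' Simulate from a fitted model
#'
#' Draws series from the fitted ARIMA process (coefficients and innovation
#' variance of the fit); exogenous terms are not simulated.
#'
#' @param object an \code{sz_fit} with \code{d = 0}.
#' @param nsim length of each simulated series.
#' @param seed integer seed.
#' @param ... unused.
#' @return numeric vector of length \code{nsim}.
#' @export
simulate.sz_fit <- function(object, nsim = object$n, seed = NULL, ...) {
  if (!object$converged) stop("cannot simulate from an unconverged fit")
  if (object$order$d != 0) stop("simulate() supports d = 0 fits only")
  if (!is.null(seed)) set.seed(as.integer(seed))
  cf <- object$coef
  mdl <- list()
  if (object$order$p > 0) mdl$ar <- unname(cf[paste0("ar", seq_len(object$order$p))])
  if (object$order$q > 0) mdl$ma <- unname(cf[paste0("ma", seq_len(object$order$q))])
  mu <- if ("intercept" %in% names(cf)) cf[["intercept"]] else 0
  as.numeric(stats::arima.sim(mdl, nsim, sd = sqrt(max(object$sigma2, 0)))) + mu
}

# Re-run the Kalman filter of a fitted model over a new history window
# (fixed coefficients, no re-estimation) and return the stats::arima object.
refilter <- function(fit, history, history_exog = NULL) {
  order <- fit$order
  rf <- suppressWarnings(
    stats::arima(history, order = c(order$p, order$d, order$q),
                 xreg = history_exog, include.mean = (order$d == 0),
                 fixed = as.numeric(fit$coef), transform.pars = FALSE,
                 method = "CSS-ML"))
  # forecast intervals must use the fitted innovation variance, not a
  # re-estimate from the short conditioning window
  rf$sigma2 <- fit$sigma2
  rf
}

#' h-step-ahead projection from a fitted model
#'
#' Conditions the fitted model (fixed coefficients) on \code{history} and
#' produces the iterated 1..\code{horizon}-step-ahead forecasts with
#' Gaussian central intervals \eqn{\pm z_{(1+level)/2}} times the forecast
#' standard error.
#'
#' @param fit an \code{sz_fit}.
#' @param history numeric vector of the most recent observations (at least
#'   the longest model lag plus one).
#' @param future_exog regressor matrix with \code{horizon} rows (required
#'   when the order uses exogenous terms).
#' @param horizon steps ahead (default 14 days).
#' @param history_exog regressors aligned with \code{history}.
#' @param level central interval coverage (default 0.95).
#' @return data frame with columns \code{step}, \code{point},
#'   \code{ci_low}, \code{ci_high}.
#' @export
project <- function(fit, history, future_exog = NULL, horizon = 14,
                    history_exog = NULL, level = 0.95) {
  if (!fit$converged) stop("cannot project from an unconverged fit")
  z <- stats::qnorm((1 + level) / 2)
  if (fit$degenerate) {
    pt <- rep(unname(fit$coef["intercept"]), horizon)
    return(data.frame(step = seq_len(horizon), point = pt, ci_low = pt,
                      ci_high = pt))
  }
  if (fit$order$use_exog) {
    if (is.null(future_exog)) stop("future exogenous regressors are required")
    future_exog <- as.matrix(future_exog)
    if (nrow(future_exog) < horizon)
      stop("future_exog must cover the full horizon")
    if (is.null(history_exog)) stop("history_exog is required with exog")
    history_exog <- as.matrix(history_exog)
  } else {
    future_exog <- NULL
    history_exog <- NULL
  }
  rf <- refilter(fit, history, history_exog)
  pr <- stats::predict(rf, n.ahead = horizon, newxreg = future_exog)
  pt <- as.numeric(pr$pred)
  se <- as.numeric(pr$se)
  data.frame(step = seq_len(horizon), point = pt, ci_low = pt - z * se,
             ci_high = pt + z * se)
}

#' Rolling daily h-step-ahead projections
#'
#' Advances the forecast origin one day at a time: at each origin the model
#' conditions on the trailing window of the longest lag plus one day (the
#' minimised input window) and projects \code{horizon} days ahead; the
#' residual is the observed value at the target date minus the projection.
#' With \code{refit_policy = "fixed"} (default) coefficients come from a
#' single fit -- either a supplied \code{fit} or one estimated on the first
#' \code{warmup} days -- and the daily update is the advancing conditioning
#' window; \code{"refit"} re-estimates coefficients each day on an enlarged
#' trailing window (longest lag + 20 + p + d + q points, the shortest
#' identifiable window).
#'
#' @param series \code{smoothed_rate}, daily \code{\link{rate_series}} or
#'   numeric vector.
#' @param order a \code{\link{model_order}} (ignored when \code{fit} is
#'   given).
#' @param cycles optional \code{cycle_set}; when the order uses exogenous
#'   terms, history regressors are taken at matching dates and future
#'   regressors are projected forward from the origin's phase at constant
#'   angular velocity.
#' @param horizon projection horizon in days (default 14).
#' @param fit optional pre-estimated \code{sz_fit} (e.g. on the training
#'   span) whose coefficients are used at every origin.
#' @param refit_policy \code{"fixed"} or \code{"refit"}.
#' @param warmup number of initial days never used as origins (default: the
#'   minimal identifiable training length when fitting internally, else the
#'   conditioning-window length).
#' @param level interval coverage (default 0.95).
#' @return A data frame of class \code{sz_projections} with one row per
#'   origin: \code{origin_date}, \code{target_date}, \code{horizon},
#'   \code{point}, \code{ci_low}, \code{ci_high}, \code{observed},
#'   \code{residual}.
#' @export
rolling_projection <- function(series, order = NULL, cycles = NULL,
                               horizon = 14, fit = NULL,
                               refit_policy = c("fixed", "refit"),
                               warmup = NULL, level = 0.95) {
  refit_policy <- match.arg(refit_policy)
  body <- series_body(series)
  x <- body$values
  dates <- body$dates
  n <- length(x)
  if (is.null(fit) && is.null(order)) stop("give either a fit or an order")
  if (!is.null(fit)) order <- fit$order
  L <- max_lag(order) + 1L
  use_exog <- order$use_exog
  reg <- NULL
  if (use_exog) {
    if (is.null(cycles)) stop("order uses exogenous terms; cycles required")
    idx <- match(as.character(dates), as.character(cycles$dates))
    if (anyNA(idx)) stop("cycle regressors do not cover the series dates")
    reg <- cycles$regressors[idx, , drop = FALSE]
    cyc_idx <- idx
  }
  min_fit_n <- order$p + order$d + order$q + 20L
  if (is.null(warmup))
    warmup <- if (is.null(fit) && refit_policy == "fixed")
      max(L, min_fit_n) else max(L, if (refit_policy == "refit") min_fit_n else L)
  warmup <- as.integer(warmup)
  if (warmup < L) stop("warmup shorter than the conditioning window")
  if (n - warmup - horizon < 1) stop("series too short for any origin")
  if (is.null(fit) && refit_policy == "fixed") {
    fit <- fit_model(x[seq_len(warmup)], order,
                     exog = if (use_exog) reg[seq_len(warmup), , drop = FALSE])
    if (!fit$converged) stop("initial model fit did not converge")
  }
  refit_win <- max(L, min_fit_n)
  origins <- seq.int(warmup + 1L, n - horizon)
  rows <- vector("list", length(origins))
  for (i in seq_along(origins)) {
    t <- origins[i]
    hist_idx <- (t - L + 1L):t
    f_t <- fit
    if (refit_policy == "refit") {
      w_idx <- max(1L, t - refit_win + 1L):t
      f_t <- fit_model(x[w_idx], order,
                       exog = if (use_exog) reg[w_idx, , drop = FALSE])
      if (!f_t$converged) next
    }
    fx <- if (use_exog)
      future_regressors(cycles, cyc_idx[t], horizon) else NULL
    pr <- project(f_t, history = x[hist_idx], future_exog = fx,
                  horizon = horizon,
                  history_exog = if (use_exog) reg[hist_idx, , drop = FALSE],
                  level = level)
    ph <- pr[horizon, ]
    obs <- x[t + horizon]
    rows[[i]] <- data.frame(origin_date = dates[t],
                            target_date = dates[t + horizon],
                            horizon = horizon, point = ph$point,
                            ci_low = ph$ci_low, ci_high = ph$ci_high,
                            observed = obs, residual = obs - ph$point)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sz_projections", "data.frame")
  out
}

#' @export
print.sz_projections <- function(x, ...) {
  cat(sprintf(
    "<sz_projections> %d daily %d-day-ahead projections (%s .. %s), MSE %.4g\n",
    nrow(x), x$horizon[1], format(x$target_date[1]),
    format(x$target_date[nrow(x)]), mse(x)))
  invisible(x)
}

#' @export
plot.sz_projections <- function(x, ..., ylab = "seizures/day") {
  plot(x$target_date, x$observed, type = "l", xlab = "date", ylab = ylab, ...)
  graphics::polygon(c(x$target_date, rev(x$target_date)),
                    c(x$ci_low, rev(x$ci_high)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(x$target_date, x$point, col = "steelblue")
  invisible(x)
}

#' Mean squared projection error
#'
#' @param records an \code{sz_projections} data frame (or anything with a
#'   \code{residual} column).
#' @return mean of squared residuals over records with an observed value.
#' @export
mse <- function(records) {
  r <- records$residual
  r <- r[is.finite(r)]
  if (!length(r)) stop("no residuals with observed values")
  mean(r^2)
}

#' Hyperparameter grid search with repeated hold-out
#'
#' For each candidate order, repeats \code{n_iter} times: draw a random
#' contiguous validation block covering \code{1 - split_frac} of the span,
#' fit on the data strictly before it, roll horizon-ahead projections
#' across the block (fixed coefficients), and score the block MSE. The best
#' order minimises the average MSE; ties break towards the smaller
#' \code{p + d + q}. Candidates that fail to converge in an iteration are
#' scored NA for it and dropped from the ranking if they never converge.
#'
#' @param series \code{smoothed_rate} (or daily series/numeric) for the
#'   train/validation span.
#' @param candidates list of \code{\link{model_order}}s.
#' @param cycles optional \code{cycle_set} for exogenous candidates.
#' @param horizon projection horizon (default 14).
#' @param n_iter hold-out repetitions (default 100).
#' @param split_frac training fraction (default 0.7).
#' @param seed integer seed for the block draws.
#' @return An object of class \code{sz_grid}: \code{best} (the selected
#'   \code{model_order}) and \code{table} (per-candidate score table).
#' @export
grid_search <- function(series, candidates, cycles = NULL, horizon = 14,
                        n_iter = 100, split_frac = 0.7, seed = 1L) {
  if (!length(candidates)) stop("candidate grid is empty")
  body <- series_body(series)
  n <- length(body$values)
  val_len <- max(horizon + 1L, round((1 - split_frac) * n))
  min_fit <- max(vapply(candidates,
                        function(o) o$p + o$d + o$q + 20L, integer(1)))
  first_start <- min_fit + 1L
  last_start <- n - val_len + 1L
  if (first_start > last_start)
    stop("series too short for the requested split")
  set.seed(as.integer(seed))
  starts <- sample(seq.int(first_start, last_start), n_iter, replace = TRUE)
  scores <- matrix(NA_real_, n_iter, length(candidates))
  for (it in seq_len(n_iter)) {
    v0 <- starts[it]
    for (ci in seq_along(candidates)) {
      ord <- candidates[[ci]]
      res <- tryCatch({
        f <- fit_model(slice_series(series, 1L, v0 - 1L), ord,
                       exog = slice_exog(cycles, body$dates, 1L, v0 - 1L,
                                         ord))
        if (!f$converged) NA_real_
        else {
          rec <- rolling_projection(series, fit = f, cycles = cycles,
                                    horizon = horizon, warmup = v0 - 1L)
          rec <- rec[rec$target_date <= body$dates[min(n, v0 + val_len - 1L)], ,
                     drop = FALSE]
          if (!nrow(rec)) NA_real_ else mse(rec)
        }
      }, error = function(e) NA_real_)
      scores[it, ci] <- res
    }
  }
  tab <- data.frame(
    p = vapply(candidates, `[[`, integer(1), "p"),
    d = vapply(candidates, `[[`, integer(1), "d"),
    q = vapply(candidates, `[[`, integer(1), "q"),
    use_exog = vapply(candidates, `[[`, logical(1), "use_exog"),
    mean_mse = colMeans(scores, na.rm = TRUE),
    n_failed = colSums(is.na(scores)))
  tab$mean_mse[!is.finite(tab$mean_mse)] <- NA_real_
  if (all(is.na(tab$mean_mse))) stop("no candidate converged")
  ord_idx <- order(tab$mean_mse, tab$p + tab$d + tab$q, na.last = TRUE)
  best <- candidates[[ord_idx[1]]]
  structure(list(best = best, table = tab[ord_idx, ], horizon = horizon,
                 n_iter = n_iter, seed = as.integer(seed)),
            class = "sz_grid")
}

#' @export
print.sz_grid <- function(x, ...) {
  cat(sprintf("<sz_grid> best: %s (avg %d-day-ahead MSE over %d hold-outs)\n",
              format(x$best), x$horizon, x$n_iter))
  print(utils::head(x$table, 10), row.names = FALSE)
  invisible(x)
}

# Index-range slice of the modelled values as a plain numeric vector.
slice_series <- function(series, from, to) {
  series_body(series)$values[from:to]
}

slice_exog <- function(cycles, dates, from, to, order) {
  if (!order$use_exog) return(NULL)
  if (is.null(cycles)) stop("exogenous candidate needs cycles")
  idx <- match(as.character(dates[from:to]), as.character(cycles$dates))
  if (anyNA(idx)) stop("cycle regressors do not cover the series dates")
  cycles$regressors[idx, , drop = FALSE]
}

#' Naive benchmark projections
#'
#' Rolling projections under the naive reference models AR(1) and MA(5)
#' (no exogenous terms), with the same protocol as
#' \code{\link{rolling_projection}}.
#'
#' @param series the modelled series.
#' @param horizon projection horizon (default 14).
#' @param warmup passed through to \code{\link{rolling_projection}}.
#' @return list with elements \code{ar1} and \code{ma5}, each an
#'   \code{sz_projections}.
#' @export
naive_benchmarks <- function(series, horizon = 14, warmup = NULL) {
  list(ar1 = rolling_projection(series, model_order(1, 0, 0),
                                horizon = horizon, warmup = warmup),
       ma5 = rolling_projection(series, model_order(0, 0, 5),
                                horizon = horizon, warmup = warmup))
}
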