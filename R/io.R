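#' Read and write the pipeline's CSV/YAML/JSON artifacts
#'
#' Event series CSV: columns \code{timestamp} (ISO-8601, UTC),
#' \code{probability}, \code{reported} (0/1). Rate series CSV: columns
#' \code{timestamp}, \code{rate}, \code{missing} (0/1). Projections CSV:
#' \code{origin_date}, \code{target_date}, \code{point}, \code{ci_low},
#' \code{ci_high}, \code{observed}, \code{residual}.
#'
#' @param x object to write.
#' @param path file path.
#' @return the input, invisibly (writers) or the parsed object (readers).
#' @name szproject-io
NULL

#' @rdname szproject-io
#' @export
write_event_series <- function(x, path) {
  df <- data.frame(timestamp = format(x$timestamp, "%Y-%m-%dT%H:%M:%OS3",
                                      tz = "UTC"),
                   probability = x$probability,
                   reported = as.integer(x$reported))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(x)
}

#' @rdname szproject-io
#' @export
read_event_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  event_series(ts,
               probability = if ("probability" %in% names(df))
                 df$probability else 1,
               reported = if ("reported" %in% names(df))
                 df$reported > 0 else FALSE)
}

#' @rdname szproject-io
#' @export
write_rate_series <- function(x, path) {
  utils::write.csv(
    data.frame(timestamp = format(rs_times(x), "%Y-%m-%dT%H:%M:%S",
                                  tz = "UTC"),
               rate = x$values, missing = as.integer(x$missing)),
    path, row.names = FALSE, quote = FALSE)
  invisible(x)
}

#' @rdname szproject-io
#' @export
read_rate_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  step_s <- if (nrow(df) > 1) as.numeric(ts[2]) - as.numeric(ts[1]) else 3600
  step <- if (isTRUE(all.equal(step_s, 86400))) "day" else "hour"
  vals <- df$rate
  miss <- if ("missing" %in% names(df)) df$missing > 0 else !is.finite(vals)
  vals[miss] <- NA_real_
  rate_series(ts[1], step, vals, miss)
}

#' @rdname szproject-io
#' @export
write_projections <- function(x, path) {
  utils::write.csv(
    data.frame(origin_date = format(x$origin_date),
               target_date = format(x$target_date),
               horizon = x$horizon, point = x$point, ci_low = x$ci_low,
               ci_high = x$ci_high, observed = x$observed,
               residual = x$residual),
    path, row.names = FALSE, quote = FALSE)
  invisible(x)
}

#' @rdname szproject-io
#' @export
read_projections <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$origin_date <- as.Date(df$origin_date)
  df$target_date <- as.Date(df$target_date)
  class(df) <- c("sz_projections", "data.frame")
  df
}

#' @rdname szproject-io
#' @export
write_sim_config <- function(x, path) {
  cfg <- unclass(x)
  cfg$start_date <- format(cfg$start_date)
  yaml::write_yaml(cfg, path)
  invisible(x)
}

#' @rdname szproject-io
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown sim_config keys: ", paste(unknown, collapse = ", "))
  do.call(sim_config, raw)
}

# Flatten an evaluation report into JSON-friendly lists.
report_to_list <- function(rep) {
  list(per_segment_mse = rep$per_segment_mse,
       kw_H = rep$kw_H, kw_df = rep$kw_df, kw_p = rep$kw_p,
       posthoc_adjusted_p = as.data.frame(rep$posthoc),
       alpha = rep$alpha,
       group_sizes = as.list(rep$group_sizes),
       block_len = rep$block_len)
}

#' @rdname szproject-io
#' @param surrogate optional surrogate \code{evaluation_report} included in
#'   the written report.
#' @param extra optional named list merged into the written report.
#' @export
write_report <- function(x, path, surrogate = NULL, extra = NULL) {
  out <- report_to_list(x)
  if (!is.null(surrogate)) out$surrogate <- report_to_list(surrogate)
  if (!is.null(extra)) out <- c(out, extra)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(x)
}
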