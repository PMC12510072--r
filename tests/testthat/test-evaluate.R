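make_records <- function(residuals, start = "2021-01-01") {
  n <- length(residuals)
  structure(data.frame(
    origin_date = as.Date(start) + seq_len(n) - 15,
    target_date = as.Date(start) + seq_len(n) - 1,
    horizon = 14, point = 0, ci_low = -1, ci_high = 1,
    observed = residuals, residual = residuals),
    class = c("sz_projections", "data.frame"))
}

test_that("segment grouping partitions records by target date", {
  rec <- make_records(rnorm(200), start = "2021-01-01")
  seg_all <- dataset_split("2021-01-01", "2021-07-19",
                           data.frame(label = "all",
                                      start = as.Date("2021-01-01"),
                                      end = as.Date("2021-07-19")))
  # one segment covering everything -> one group of full size (train aside)
  g <- segment_residuals(rec, seg_all, include_train = FALSE)
  expect_equal(lengths(g), c(all = 200L))

  seg2 <- dataset_split("2021-05-01", "2021-06-01", data.frame(
    label = c("a", "b"),
    start = as.Date(c("2021-01-01", "2021-02-15")),
    end = as.Date(c("2021-01-31", "2021-03-15"))))
  g2 <- segment_residuals(rec, seg2, include_train = FALSE)
  expect_lte(sum(lengths(g2)), 200)
  expect_equal(length(intersect(g2$a, g2$b)), 0L)

  seg_empty <- dataset_split("2021-01-01", "2021-01-31", data.frame(
    label = "future", start = as.Date("2030-01-01"),
    end = as.Date("2030-03-01")))
  expect_warning(segment_residuals(rec, seg_empty, include_train = FALSE),
                 "no records")

  expect_error(dataset_split("2021-01-01", "2021-02-01", data.frame(
    label = c("x", "y"), start = as.Date(c("2021-01-01", "2021-01-15")),
    end = as.Date(c("2021-01-20", "2021-02-01")))), "overlap")
})

test_that("omnibus test matches hand-computed rank arithmetic", {
  same <- list(a = rep(1, 5), b = rep(1, 5))
  expect_equal(suppressWarnings(omnibus_and_posthoc(same))$kw_H, 0)

  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  rep <- omnibus_and_posthoc(g)
  # hand ranking: mean ranks 2, 5, 8 -> H = 12/90 * 3*(9+0+9) = 7.2
  expect_equal(rep$kw_H, 7.2)
  expect_equal(rep$kw_df, 2)

  five <- split(rnorm(50), rep(1:5, each = 10))
  expect_equal(omnibus_and_posthoc(five)$kw_df, 4)

  expect_error(omnibus_and_posthoc(list(a = 1:3)), "at least 2 groups")
})

test_that("Bonferroni adjustment is capped and monotone", {
  set.seed(3)
  g <- list(a = rnorm(10), b = rnorm(10, 2), c = rnorm(10, 4))
  rep <- omnibus_and_posthoc(g)
  expect_true(all(rep$posthoc[upper.tri(rep$posthoc)] <= 1))
  expect_true(all(rep$posthoc >= rep$posthoc_raw, na.rm = TRUE))
  ord_raw <- order(rep$posthoc_raw[upper.tri(rep$posthoc_raw)])
  ord_adj <- order(rep$posthoc[upper.tri(rep$posthoc)])
  expect_equal(ord_raw, ord_adj)
  expect_equal(rep$posthoc, t(rep$posthoc))
})

test_that("surrogate shuffling preserves values and is seed-deterministic", {
  s <- daily_series(rnorm(100, 10))
  a <- surrogate_series(s, seed = 4)
  b <- surrogate_series(s, seed = 4)
  expect_identical(a$values, b$values)
  expect_equal(sort(a$values), sort(s$values))
  expect_false(identical(a$values, s$values))
})

test_that("shuffling destroys the autocorrelation a model could exploit", {
  set.seed(21)
  wins <- 0
  for (s in 1:5) {
    x <- as.numeric(arima.sim(list(ar = 0.9), 400)) + 10
    sh <- surrogate_series(daily_series(x), seed = s)
    rec <- rolling_projection(sh, model_order(1, 0, 0), horizon = 1,
                              warmup = 100)
    if (abs(mse(rec) / var(sh$values) - 1) < 0.1) wins <- wins + 1
  }
  expect_gte(wins, 3)
})

test_that("residual monitoring flags excursions with persistence", {
  set.seed(6)
  ref <- rnorm(100)
  inband <- make_records(rnorm(60, 0, 1) * 0.5)
  m0 <- monitor_residuals(inband, ref, k_sd = 3, persistence_days = 14)
  expect_equal(sum(m0$flags), 0L)
  expect_equal(length(m0$changepoints), 0L)

  # 30-day +5 SD excursion -> exactly one onset and one return changepoint
  r <- c(rnorm(60) * 0.5, rnorm(30, 5 * sd(ref), 0.1), rnorm(60) * 0.5)
  rec <- make_records(r)
  m <- monitor_residuals(rec, ref, k_sd = 3, persistence_days = 14)
  expect_equal(length(m$changepoints), 2L)
  expect_equal(m$changepoints[1], as.Date("2021-01-01") + 60)
  expect_equal(m$changepoints[2], as.Date("2021-01-01") + 90)

  # an effectively infinite band never flags
  mwide <- monitor_residuals(rec, ref, k_sd = 1e6, persistence_days = 14)
  expect_equal(sum(mwide$flags), 0L)

  expect_error(monitor_residuals(rec, rep(1, 50)), "SD is zero")
  expect_error(monitor_residuals(rec, rnorm(10)), "at least 30")
})

test_that("reporting concordance is the rounded detected fraction", {
  det <- events_at(seq(0, 99, length.out = 3122))
  rep <- det[seq_len(1169), ]
  expect_equal(reporting_concordance(det, rep), 37.44)
  expect_equal(reporting_concordance(det, det[0, ]), 0.00)
  det14 <- events_at(1:14)
  expect_equal(reporting_concordance(det14, det14[1:4, ]), 28.57)
  expect_error(reporting_concordance(det[0, ], det[0, ]), "no detected")
})
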