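test_that("model orders validate and the random walk is admitted", {
  expect_s3_class(model_order(0, 1, 0), "model_order")
  expect_error(model_order(0, 0, 0), "p \\+ d \\+ q")
  expect_error(model_order(-1, 0, 1), "invalid")
  expect_equal(format(model_order(51, 1, 1, use_exog = TRUE)),
               "ARIMAX(51,1,1)")
})

test_that("h-step projections match closed-form forecast oracles", {
  set.seed(2)
  x <- as.numeric(arima.sim(list(ar = 0.7), 200))

  # AR(1), zero mean, known phi: x_hat(t+h) = phi^h x_t
  f <- fit_model(x, model_order(1, 0, 0), fixed = c(0.7, 0))
  pr <- project(f, history = tail(x, 2), horizon = 10)
  expect_equal(pr$point, 0.7^(1:10) * x[200], tolerance = 1e-8)

  # random walk: forecast = last value, exactly
  rw <- cumsum(rnorm(100))
  frw <- fit_model(rw, model_order(0, 1, 0))
  prw <- project(frw, history = tail(rw, 3), horizon = 14)
  expect_identical(unique(prw$point), rw[100])

  # MA(q) memory cutoff: beyond q steps the forecast is the mean (0)
  ma <- as.numeric(arima.sim(list(ma = c(0.5, 0.3)), 200))
  fma <- fit_model(ma, model_order(0, 0, 2), fixed = c(0.5, 0.3, 0))
  pma <- project(fma, history = tail(ma, 5), horizon = 6)
  expect_equal(pma$point[3:6], rep(0, 4), tolerance = 1e-10)

  # intervals are central: ci_low <= point <= ci_high
  expect_true(all(pr$ci_low <= pr$point & pr$point <= pr$ci_high))
})

test_that("constant series yields a degenerate but usable fit", {
  f <- fit_model(rep(2.5, 100), model_order(1, 0, 0))
  expect_true(f$converged)
  expect_true(f$degenerate)
  expect_equal(unname(f$coef["intercept"]), 2.5)
  expect_equal(f$sigma2, 0)
  pr <- project(f, history = rep(2.5, 3), horizon = 5)
  expect_equal(pr$point, rep(2.5, 5))
  expect_equal(pr$ci_low, pr$ci_high)
})

test_that("AR and exogenous coefficients are recovered consistently", {
  set.seed(31)
  x <- as.numeric(arima.sim(list(ar = 0.7), 2000))
  f <- fit_model(x, model_order(1, 0, 0))
  expect_true(f$converged)
  expect_gt(unname(f$coef["ar1"]), 0.65)
  expect_lt(unname(f$coef["ar1"]), 0.75)

  # y = 2 sin(phase) + AR(1) noise: exog coefficient within 2 SE of 2
  phi <- 2 * pi * (1:1000) / 20
  y <- 2 * sin(phi) + as.numeric(arima.sim(list(ar = 0.5), 1000))
  reg <- cbind(sin_20 = sin(phi), cos_20 = cos(phi))
  fx <- fit_model(y, model_order(1, 0, 0, use_exog = TRUE), exog = reg)
  est <- unname(fx$coef["sin_20"])
  se <- sqrt(diag(fx$fit$var.coef))[["sin_20"]]
  expect_lt(abs(est - 2), 2 * se)
})

test_that("rolling projections have the expected layout and residuals", {
  # deterministic (constant) series followed exactly -> all residuals 0
  const <- daily_series(rep(2, 120))
  rec <- rolling_projection(const, model_order(1, 0, 0), horizon = 14,
                            warmup = 40)
  expect_equal(nrow(rec), 120 - 40 - 14)
  expect_equal(rec$residual, rep(0, nrow(rec)))
  expect_equal(as.Date(rec$target_date[1]),
               as.Date("2020-01-01") + 40 + 14)

  # white noise under an AR(1) model: residual variance ~ series variance
  set.seed(8)
  wn <- rnorm(400)
  recw <- rolling_projection(wn, model_order(1, 0, 0), horizon = 1,
                             warmup = 100)
  expect_lt(abs(mse(recw) / var(wn) - 1), 0.25)
})

test_that("interval coverage is near nominal at one step ahead", {
  set.seed(99)
  hits <- numeric(0)
  for (s in 1:4) {
    x <- as.numeric(arima.sim(list(ar = 0.6), 500))
    rec <- rolling_projection(x, model_order(1, 0, 0), horizon = 1,
                              warmup = 100)
    hits <- c(hits, rec$observed >= rec$ci_low & rec$observed <= rec$ci_high)
  }
  expect_gt(mean(hits), 0.92)
  expect_lt(mean(hits), 0.97)
})

test_that("mse is the mean of squared residuals", {
  rec <- data.frame(residual = c(1, -1))
  expect_equal(mse(rec), 1.0)
  expect_equal(mse(data.frame(residual = 0.3)), 0.09)
  expect_equal(mse(data.frame(residual = rep(0, 5))), 0)
  expect_error(mse(data.frame(residual = NA_real_)), "no residuals")
})

test_that("grid search selects sensible orders reproducibly", {
  set.seed(17)
  x <- as.numeric(arima.sim(list(order = c(2, 1, 0), ar = c(0.6, 0.25)),
                            300))
  single <- grid_search(x, list(model_order(1, 0, 0)), n_iter = 5, seed = 1)
  expect_equal(format(single$best), "ARIMA(1,0,0)")

  grid <- list(model_order(1, 0, 0), model_order(1, 1, 0),
               model_order(2, 1, 0))
  wins <- 0
  for (s in 1:5) {
    xs <- as.numeric(arima.sim(list(order = c(2, 1, 0),
                                    ar = c(0.6, 0.25)), 300))
    g <- grid_search(xs, grid, horizon = 5, n_iter = 10, seed = s)
    if (g$best$p >= 2 && g$best$d == 1) wins <- wins + 1
  }
  expect_gte(wins, 3)

  g1 <- grid_search(x, grid, horizon = 5, n_iter = 10, seed = 4)
  g2 <- grid_search(x, grid, horizon = 5, n_iter = 10, seed = 4)
  expect_identical(g1$table, g2$table)
})

test_that("naive benchmarks follow the shared rolling protocol", {
  const <- daily_series(rep(1.5, 150))
  nb <- naive_benchmarks(const, horizon = 14, warmup = 50)
  expect_equal(mse(nb$ar1), 0)
  expect_equal(mse(nb$ma5), 0)

  # model-match: AR(1) data favours the AR(1) naive model
  wins <- 0
  for (s in 1:5) {
    set.seed(s + 40)
    x <- as.numeric(arima.sim(list(ar = 0.8), 400))
    nb <- naive_benchmarks(x, horizon = 5, warmup = 100)
    if (mse(nb$ar1) <= mse(nb$ma5)) wins <- wins + 1
  }
  expect_gte(wins, 3)
})
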