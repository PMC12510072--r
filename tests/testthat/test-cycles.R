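test_that("wavelet spectrum localises a pure sinusoid and zeroes on silence", {
  zero <- daily_series(rep(0, 365))
  spec <- morlet_cwt(zero, cycle_periods(2, 45))
  expect_true(all(spec$power == 0))

  cosine <- hourly_cosine(20, 365)
  spec <- morlet_cwt(cosine)
  peak <- spec$periods[which.max(spec$global_power)]
  expect_true(within_scale_step(peak, 20))

  # >= 50% of total (COI-free) power within one octave of the true scale
  ok <- !spec$coi_excluded
  tot <- sum(spec$power[ok])
  near <- abs(log2(spec$periods / 20)) <= 1
  expect_gt(sum(spec$power[near, ][ok[near, ]]) / tot, 0.5)

  expect_error(morlet_cwt(daily_series(rnorm(50)), cycle_periods(2, 45)),
               "twice the longest")
})

test_that("phase extraction matches the analytic phase of sinusoids", {
  n_days <- 200
  t <- (seq_len(n_days * 24) - 1) / 24
  centre <- 100 * 24 + 1
  cosx <- rate_series(utc("2020-01-01"), "hour",
                      10 + cos(2 * pi * (t - 100) / 20))
  ph <- extract_phase(cosx, 20)
  expect_lt(abs(ph[centre]), 0.05)

  sinx <- rate_series(utc("2020-01-01"), "hour",
                      10 + sin(2 * pi * (t - 100) / 20))
  ph_s <- extract_phase(sinx, 20)
  expect_lt(abs(ph_s[centre] - (-pi / 2)), 0.05)

  # winding-number property: phase increments over one period sum to 2 pi
  one_period <- ph[centre:(centre + 20 * 24)]
  incr <- diff(one_period)
  incr <- incr - 2 * pi * round(incr / (2 * pi))  # unwrap
  expect_lt(abs(sum(incr) - 2 * pi) / (2 * pi), 0.01)
})

test_that("phase regressors sit on the unit circle in the stated order", {
  reg0 <- build_phase_regressors(matrix(0, 5, 1), periods = 20)
  expect_equal(unname(reg0), cbind(rep(0, 5), rep(1, 5)))
  expect_equal(colnames(reg0), c("sin_20", "cos_20"))

  regq <- build_phase_regressors(matrix(pi / 2, 5, 1), periods = 20)
  expect_equal(unname(regq), cbind(rep(1, 5), rep(0, 5)), tolerance = 1e-12)

  set.seed(1)
  ph <- matrix(runif(60, -pi, pi), 20, 3)
  reg <- build_phase_regressors(ph, periods = c(5, 10, 20))
  for (j in 1:3)
    expect_equal(reg[, 2 * j - 1]^2 + reg[, 2 * j]^2, rep(1, 20),
                 tolerance = 1e-12)
})

test_that("phase projection advances at constant angular velocity", {
  expect_equal(project_phases(0.7, 20, 0), 0.7)
  ph <- project_phases(0.7, 20, 20)
  expect_equal(ph[20], 0.7, tolerance = 1e-9)       # full turn
  expect_equal(abs(project_phases(0.7, 20, 10)[10] - 0.7), pi,
               tolerance = 1e-9)                     # half turn antipodal
  expect_true(all(ph > -pi & ph <= pi + 1e-12))
})

test_that("permutation significance is deterministic and finds a strong cycle", {
  set.seed(100)
  x <- 10 + 3 * cos(2 * pi * (1:730) / 20) + rnorm(730, 0, 3)
  s <- daily_series(x)
  det1 <- permutation_significance(s, cycle_periods(2, 45), n_perm = 200,
                                   seed = 5)
  det2 <- permutation_significance(s, cycle_periods(2, 45), n_perm = 200,
                                   seed = 5)
  expect_identical(det1$significant_periods, det2$significant_periods)
  expect_identical(det1$p, det2$p)
  expect_true(within_scale_step(det1$significant_periods, 20))

  # contiguous significant runs collapse to local power maxima
  expect_lte(length(det1$significant_periods), sum(det1$significant))
})

test_that("detect_cycles assembles phases and regressors for detected periods", {
  cfg <- sim_config(n_days = 400, cycles = list(c(20, 0.3, 0)),
                    ied_cycle_gain = 0.3, ied_noise_sd = 6,
                    drug_change_day = NULL, gaps = list(), seed = 2)
  ied <- simulate_ied_rates(cfg, seed = 2)
  cyc <- detect_cycles(ied, cycle_periods(2, 45), n_perm = 200, seed = 3)
  expect_true(length(cyc$significant_periods) >= 1)
  expect_true(within_scale_step(cyc$significant_periods, 20))
  expect_equal(nrow(cyc$regressors), 400L)
  expect_equal(ncol(cyc$regressors),
               2L * length(cyc$significant_periods))
  ss <- cyc$regressors[, 1]^2 + cyc$regressors[, 2]^2
  expect_equal(ss, rep(1, 400), tolerance = 1e-12)
})
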