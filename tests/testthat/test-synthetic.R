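test_that("intensity follows the multiplicative-cosine closed form", {
  flat <- sim_config(n_days = 10, baseline_rate = 2, cycles = list(),
                     ied_cycle_gain = numeric(0), drug_change_day = NULL,
                     gaps = list())
  expect_equal(simulate_intensity(flat), rep(2, 10))

  one <- sim_config(n_days = 40, baseline_rate = 2,
                    cycles = list(c(20, 0.5, 0)), ied_cycle_gain = 0.3,
                    drug_change_day = NULL, gaps = list())
  lam <- simulate_intensity(one)
  expect_equal(lam[1], 3.0)   # day 0: cos(0) = 1
  expect_equal(lam[11], 1.0)  # day 10: cos(pi) = -1

  step <- sim_config(n_days = 200, baseline_rate = 2, cycles = list(),
                     ied_cycle_gain = numeric(0), drug_change_day = 100,
                     drug_effect = 0.5, drug_transient = NULL, gaps = list())
  lam <- simulate_intensity(step)
  expect_equal(lam[100] / lam[101], 2)  # day 99 vs day 100 (0-based)

  expect_error(sim_config(cycles = list(c(20, 0.6, 0), c(5, 0.5, 0)),
                          ied_cycle_gain = c(0.1, 0.1)),
               "sum below 1")
})

test_that("drug transient applies a temporary extra factor", {
  cfg <- sim_config(n_days = 420, baseline_rate = 2, cycles = list(),
                    ied_cycle_gain = numeric(0), drug_change_day = 100,
                    drug_effect = 0.8,
                    drug_transient = list(duration = 30, factor = 0.5),
                    gaps = list())
  lam <- simulate_intensity(cfg)
  expect_equal(lam[95], 2)            # pre-drug
  expect_equal(lam[105], 2 * 0.8 * 0.5)  # titration dip
  expect_equal(lam[200], 2 * 0.8)     # chronic effect after tolerance
})

test_that("event simulation is Poisson-consistent and seed-deterministic", {
  expect_equal(nrow(simulate_events(numeric(0), seed = 1)), 0L)

  ev <- simulate_events(rep(2, 1000), seed = 42)
  expect_lt(abs(nrow(ev) - 2000), 3 * sqrt(2000))
  expect_true(all(diff(as.numeric(ev$timestamp)) >= 0))

  ev2 <- simulate_events(rep(2, 1000), seed = 42)
  expect_identical(ev$timestamp, ev2$timestamp)
})

test_that("realised mean daily count converges to the mean intensity", {
  cfg <- sim_config(n_days = 3000, drug_change_day = NULL, gaps = list())
  lam <- simulate_intensity(cfg)
  ev <- simulate_events(lam, seed = 7)
  expect_lt(abs(nrow(ev) / 3000 - mean(lam)) / mean(lam), 0.05)
})

test_that("IED simulation phase-locks cycles and marks gap samples", {
  const <- sim_config(n_days = 60, cycles = list(),
                      ied_cycle_gain = numeric(0), ied_noise_sd = 0,
                      ied_baseline = 30, drug_change_day = NULL,
                      gaps = list())
  r <- simulate_ied_rates(const, seed = 1)
  expect_equal(unique(r$values), 30)

  one <- sim_config(n_days = 60, cycles = list(c(20, 0.3, 0)),
                    ied_cycle_gain = 0.4, ied_noise_sd = 0,
                    drug_change_day = NULL, gaps = list())
  r <- simulate_ied_rates(one, seed = 1)
  expect_equal(which.max(r$values[1:(20 * 24)]), 1L)  # peak at phase 0

  gapped <- sim_config(n_days = 100, cycles = list(),
                       ied_cycle_gain = numeric(0), drug_change_day = NULL,
                       gaps = list(c(50, 10)))
  r <- simulate_ied_rates(gapped, seed = 1)
  expect_equal(sum(r$missing), 240L)  # 10 days x 24 h
  expect_true(all(which(r$missing) == 50 * 24 + 1:240))
})

test_that("diary thinning keeps a binomial fraction and is a subset", {
  ev <- events_at(seq(0, 99.9, length.out = 400))
  expect_equal(nrow(simulate_diary(ev, 1, seed = 1)), 400L)
  expect_equal(nrow(simulate_diary(ev, 0, seed = 1)), 0L)

  d <- simulate_diary(ev, 0.4, seed = 5)
  expect_true(all(d$timestamp %in% ev$timestamp))
  expect_true(all(d$reported))

  # binomial mean over replicates: 3122 events thinned at the reported rate
  big <- events_at(seq(0, 999, length.out = 3122))
  kept <- vapply(1:200, function(s)
    nrow(simulate_diary(big, 0.3744, seed = s)), numeric(1))
  se <- sqrt(3122 * 0.3744 * (1 - 0.3744) / 200)
  expect_lt(abs(mean(kept) - 3122 * 0.3744), 4 * se)
})

test_that("a simulated participant satisfies its structural invariants", {
  p <- simulate_participant(sim_config(n_days = 1100, seed = 11))
  expect_true(all(p$diary_events$timestamp %in% p$seizure_events$timestamp))
  span <- utc("2020-01-01") + c(0, 1100) * 86400
  expect_true(all(p$seizure_events$timestamp >= span[1] &
                    p$seizure_events$timestamp < span[2]))
  expect_equal(p$regimen_intervals$label, c("pre-drug", "post-drug"))

  p2 <- simulate_participant(sim_config(n_days = 1100, seed = 11))
  expect_identical(p$seizure_events, p2$seizure_events)
  expect_identical(p$ied_rates$values, p2$ied_rates$values)
})
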