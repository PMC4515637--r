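test_that("perievent z-scores are standardized against the baseline", {
  ev <- seq(20, 980, by = 10)
  flat <- simulate_perievent_train(5, ev, duration = 1000, seed = 101)
  r <- perievent_zscore(flat, ev)
  expect_equal(length(r$z), 100L)
  expect_equal(r$edges[1], -5); expect_equal(r$edges[101], 5)
  base <- r$z[r$centers < 0]
  expect_equal(mean(base), 0, tolerance = 1e-10)
  expect_equal(sd(base), 1, tolerance = 1e-10)
  post <- r$z[r$centers > 0]
  expect_lt(abs(mean(post)), 0.75)
  expect_error(perievent_zscore(flat, ev[1:3]), "5 events")
  expect_error(perievent_zscore(flat, ev, baseline = c(-10, 0)),
               "within the analysis window")
  silent <- spike_train("s", c(1, 2))
  expect_error(perievent_zscore(silent, ev), "SD is zero")
})

test_that("rate steps produce the expected z-sign in the stepped window", {
  ev <- seq(20, 1980, by = 10)
  up <- simulate_perievent_train(
    5, ev, profile = data.frame(start = 0, end = 0.5, multiplier = 3),
    duration = 2000, seed = 102)
  r <- perievent_zscore(up, ev)
  expect_gt(mean(r$z[r$centers > 0 & r$centers < 0.5]), 2)
  expect_lt(abs(mean(r$z[r$centers > 2])), 1)
})

test_that("responses are subcategorized over Early and Middle windows", {
  ev <- seq(20, 1980, by = 10)
  exc_inh <- simulate_perievent_train(
    5, ev, profile = data.frame(start = c(0, 0.5), end = c(0.5, 2),
                                multiplier = c(3, 0.05)),
    duration = 2000, seed = 103)
  expect_equal(classify_response(perievent_zscore(exc_inh, ev))$label,
               "Exc-Inh")
  inh_only <- simulate_perievent_train(
    5, ev, profile = data.frame(start = 0, end = 0.5, multiplier = 0),
    duration = 2000, seed = 104)
  expect_equal(classify_response(perievent_zscore(inh_only, ev))$label,
               "Inh-None")
  flat <- simulate_perievent_train(5, ev, duration = 2000, seed = 105)
  expect_equal(classify_response(perievent_zscore(flat, ev))$label,
               "None-None")
  r <- perievent_zscore(flat, ev)
  expect_error(classify_response(r, early = c(0, 1), middle = c(0.5, 2)),
               "disjoint")
})

test_that("classification is invariant to a time-unit change that preserves
           bin counts", {
  ev <- seq(20, 1980, by = 10)
  tr <- simulate_perievent_train(
    5, ev, profile = data.frame(start = c(0, 0.5), end = c(0.5, 2),
                                multiplier = c(3, 0.05)),
    duration = 2000, seed = 106)
  r_s <- perievent_zscore(tr, ev)
  # same train expressed in deciseconds: 10x times, 10x windows and bins
  tr_ds <- spike_train(tr$unit_id, tr$times * 10)
  r_ds <- perievent_zscore(tr_ds, ev * 10, window = c(-50, 50), bin = 1,
                           baseline = c(-50, 0))
  expect_equal(r_ds$z, r_s$z, tolerance = 1e-10)
  expect_equal(
    classify_response(r_ds, early = c(0, 5), middle = c(5, 20))$label,
    classify_response(r_s)$label)
})

test_that("first-spike latency summarizes responsive pulses only", {
  pulses <- seq(10, 209, by = 1)
  exact <- spike_train("u", pulses + 0.003)
  lat <- first_spike_latency(exact, pulses)
  expect_equal(lat$mean_ms, 3, tolerance = 1e-9)
  expect_equal(lat$sem_ms, 0, tolerance = 1e-9)
  expect_equal(lat$n_responsive, 200L)

  set.seed(107)
  jit <- pmax(pmin(rnorm(200, 0.00374, 0.0008), 0.0099), 0.0002)
  jittered <- spike_train("u", pulses + jit)
  lat2 <- first_spike_latency(jittered, pulses)
  expect_equal(lat2$n_responsive, 200L)
  expect_lt(abs(lat2$mean_ms - 3.74), 2 * lat2$sem_ms + 0.2)

  none <- spike_train("u", pulses + 0.5)
  expect_warning(lat3 <- first_spike_latency(none, pulses), "no responsive")
  expect_true(is.na(lat3$mean_ms))
  expect_error(first_spike_latency(exact, numeric(0)), "pulse")
})
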