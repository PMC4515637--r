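test_that("gamma-renewal trains have the prescribed ISI statistics", {
  # k = 1 reduces to a Poisson process: exponential ISIs
  tr <- simulate_gamma_train(1, 0.2, 2100, seed = 3)
  isis <- compute_isis(tr)[1:10000]
  ks <- suppressWarnings(ks.test(isis, "pexp", rate = 1 / 0.2))
  expect_gt(ks$p.value, 0.01)
  # cv of gamma ISIs is 1/sqrt(k)
  tr4 <- simulate_gamma_train(4, 0.05, 2100, seed = 4)
  isis4 <- compute_isis(tr4)[1:10000]
  expect_equal(compute_cv(isis4), 0.5, tolerance = 0.03 / 0.5)
  # mean ISI converges to k * theta
  expect_equal(mean(isis4), 0.2, tolerance = 0.02)
})

test_that("generators are deterministic under a fixed seed", {
  expect_identical(simulate_gamma_train(2, 0.1, 50, seed = 9)$times,
                   simulate_gamma_train(2, 0.1, 50, seed = 9)$times)
  expect_identical(
    simulate_burst_train(1, 3L, 0.005, duration = 100, seed = 5)$times,
    simulate_burst_train(1, 3L, 0.005, duration = 100, seed = 5)$times)
  expect_identical(
    simulate_lfp(data.frame(freq = 4, amplitude = 1, start = 0, end = 10),
                 fs = 50, duration = 10, seed = 2)$samples,
    simulate_lfp(data.frame(freq = 4, amplitude = 1, start = 0, end = 10),
                 fs = 50, duration = 10, seed = 2)$samples)
  ev <- seq(5, 95, by = 5)
  expect_identical(
    simulate_perievent_train(5, ev, duration = 100, seed = 1)$times,
    simulate_perievent_train(5, ev, duration = 100, seed = 1)$times)
})

test_that("generator preconditions are enforced", {
  expect_error(simulate_gamma_train(0, 0.1, 10), "positive")
  expect_error(simulate_gamma_train(1, -1, 10), "positive")
  expect_error(simulate_burst_train(1, 3L, 0.02, duration = 10), "0.010")
  expect_error(simulate_burst_train(200, 3L, 0.006, duration = 10),
               "burst spacing")
  expect_error(simulate_lfp(data.frame(freq = 30, amplitude = 1, start = 0,
                                       end = 10), fs = 50, duration = 10),
               "Nyquist")
  expect_error(simulate_perievent_train(
    5, c(10, 20), profile = data.frame(start = c(0, 0.2), end = c(0.5, 0.7),
                                       multiplier = c(2, 2)), duration = 50),
    "overlap")
  expect_error(simulate_population(list(), seed = 1), "non-empty")
})

test_that("burst trains hit the closed-form burst index", {
  # fixed 3 spikes per burst: 2 of every 3 ISIs are intra-burst
  tr <- simulate_burst_train(1, 3L, 0.005, duration = 4000, seed = 11)
  bi <- burst_index(compute_isis(tr))
  expect_equal(bi, 2 / 3, tolerance = 0.02)
  # 1 spike per burst degenerates to a Poisson process
  tr1 <- simulate_burst_train(2, 1L, 0.005, duration = 2000, seed = 12)
  expect_lt(burst_index(compute_isis(tr1)), 0.05)
  isis1 <- compute_isis(tr1)
  ks <- suppressWarnings(ks.test(isis1, "pexp", rate = 2))
  expect_gt(ks$p.value, 0.01)
})

test_that("bursty trains break the renewal coupling: fitted k < 1 and
           cv exceeds 1/sqrt(k)", {
  tr <- simulate_burst_train(0.8, 4L, 0.004, duration = 3000, seed = 13)
  isis <- compute_isis(tr)
  fit <- fit_gamma_mle(isis)
  expect_lt(fit$k, 1)
  expect_gt(compute_cv(isis) * sqrt(fit$k), 1.1)
})

test_that("population generation is stable bookkeeping with substreams", {
  pop <- simulate_population(ca1_like_subtypes, duration = 300, seed = 21)
  expect_length(pop$set$trains, 60L)
  expect_equal(nrow(pop$labels), 60L)
  expect_equal(unname(table(pop$labels$subtype)), c(30L, 30L),
               ignore_attr = TRUE)
  # adding a subtype leaves earlier units untouched
  pop2 <- simulate_population(c(ca1_like_subtypes,
                                list(list(name = "extra", n_units = 5,
                                          k_range = c(2, 3),
                                          rate_range = c(5, 8),
                                          process = "gamma"))),
                              duration = 300, seed = 21)
  expect_identical(pop$set$trains$u001$times, pop2$set$trains$u001$times)
  expect_identical(pop$set$trains$u060$times, pop2$set$trains$u060$times)
})

test_that("scheduled LFP components dominate their bands on schedule", {
  comps <- data.frame(freq = c(2, 8), amplitude = c(3, 3),
                      start = c(0, 60), end = c(60, 120))
  lfp <- simulate_lfp(comps, fs = 100, duration = 120, noise_sd = 0.5,
                      seed = 6)
  r <- band_power_ratio(lfp, numerator = "delta")
  first_half <- r$ratio[r$t_end <= 60]
  second_half <- r$ratio[r$t_start >= 60]
  expect_gt(median(first_half), 10)
  expect_lt(median(second_half), 0.1)
})

test_that("perievent trains follow their rate profile", {
  ev <- seq(20, 980, by = 10)
  up <- simulate_perievent_train(
    5, ev, profile = data.frame(start = 0, end = 0.5, multiplier = 3),
    duration = 1000, seed = 7)
  r <- perievent_zscore(up, ev)
  expect_gt(mean(r$z[r$centers > 0 & r$centers < 0.5]), 2)
  down <- simulate_perievent_train(
    5, ev, profile = data.frame(start = 0, end = 0.5, multiplier = 0),
    duration = 1000, seed = 8)
  rd <- perievent_zscore(down, ev)
  expect_lt(mean(rd$z[rd$centers > 0 & rd$centers < 0.5]), -2)
  flat <- simulate_perievent_train(5, ev, duration = 1000, seed = 9)
  rf <- perievent_zscore(flat, ev)
  expect_lt(abs(mean(rf$z[rf$centers > 0])), 1)
})
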