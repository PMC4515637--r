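test_that("ISI computation handles short trains and masks", {
  expect_equal(compute_isis(spike_train("u", c(1, 1.5, 3))), c(0.5, 1.5))
  expect_equal(compute_isis(spike_train("u", 2)), numeric(0))
  expect_equal(compute_isis(spike_train("u", numeric(0))), numeric(0))
  tr <- spike_train("u", c(1, 2, 8, 9))
  r <- restrict_to_epochs(tr, epoch_set(c(0, 7), c(3, 10), c("a", "a")), "a")
  expect_equal(compute_isis(r), c(1, 1))
  expect_error(compute_isis(tr, mask = c(TRUE, FALSE)), "length")
})

test_that("coefficient of variation follows its definition", {
  expect_equal(compute_cv(c(1, 2, 3)), 0.5)  # sample sd 1, mean 2
  expect_equal(compute_cv(rep(0.3, 50)), 0)
  set.seed(31)
  isis <- rexp(10000, rate = 5)
  expect_equal(compute_cv(isis), 1, tolerance = 0.02)
  expect_error(compute_cv(0.5), "at least 2")
})

test_that("cv and the gamma fit are invariant to time rescaling", {
  set.seed(32)
  isis <- rgamma(2000, shape = 1.6, scale = 0.08)
  for (c0 in c(0.001, 7.3)) {
    expect_equal(compute_cv(c0 * isis), compute_cv(isis))
    f1 <- fit_gamma_mle(isis); f2 <- fit_gamma_mle(c0 * isis)
    expect_equal(f2$k, f1$k, tolerance = 1e-9)
    expect_equal(f2$theta, c0 * f1$theta, tolerance = 1e-9)
  }
})

test_that("gamma MLE solves the digamma equation and beats both the
           method-of-moments start and a grid-search oracle", {
  set.seed(33)
  for (k_true in c(0.5, 1, 2, 4)) {
    isis <- rgamma(5000, shape = k_true, scale = 0.05)
    fit <- fit_gamma_mle(isis)
    expect_equal(fit$k, k_true, tolerance = 0.08)
    expect_equal(fit$theta, 0.05, tolerance = 0.1)
    # stationarity of the profile likelihood
    s <- log(mean(isis)) - mean(log(isis))
    expect_lt(abs(log(fit$k) - digamma(fit$k) - s), 1e-8)
    # not worse than the independent grid maximizer
    g <- grid_gamma_fit(isis)
    expect_gte(fit$loglik, g$loglik - 1e-6)
    expect_equal(fit$k, g$k, tolerance = 1e-3 / g$k)
    # and at least as good as the method-of-moments start
    k0 <- mean(isis)^2 / var(isis)
    ll0 <- sum(dgamma(isis, shape = k0, scale = mean(isis) / k0, log = TRUE))
    expect_gte(fit$loglik, ll0)
  }
})

test_that("gamma MLE agrees with an independent fitting package", {
  set.seed(34)
  isis <- rgamma(3000, shape = 2.3, scale = 0.04)
  fit <- fit_gamma_mle(isis)
  ref <- fitdistrplus::fitdist(isis, "gamma")
  expect_equal(fit$k, unname(ref$estimate["shape"]), tolerance = 1e-4)
  expect_equal(1 / fit$theta, unname(ref$estimate["rate"]), tolerance = 1e-3)
})

test_that("the >250-ISI rule is enforced strictly", {
  set.seed(35)
  expect_false(fit_gamma_mle(rgamma(100, 1, 1))$fit_ok)
  expect_false(fit_gamma_mle(rgamma(250, 1, 1))$fit_ok)  # boundary: not >
  expect_true(fit_gamma_mle(rgamma(251, 1, 1))$fit_ok)
  expect_error(fit_gamma_mle(c(rgamma(300, 1, 1), 0)), "positive")
  expect_error(fit_gamma_mle(rep(0.5, 300)), "unbounded|variance")
})

test_that("burst index counts strictly sub-threshold ISIs", {
  expect_equal(burst_index(rep(0.005, 10)), 1)
  expect_equal(burst_index(c(0.020, 0.030)), 0)
  expect_equal(burst_index(c(0.005, 0.015, 0.008, 0.2)), 0.5)
  expect_equal(burst_index(c(0.010, 0.005)), 0.5)  # boundary 10 ms not a burst
  expect_error(burst_index(numeric(0)), "empty")
  # monotone non-decreasing in the threshold
  set.seed(36)
  isis <- rexp(500, 50)
  ths <- c(0.005, 0.01, 0.02, 0.05)
  bis <- vapply(ths, function(t) burst_index(isis, t), numeric(1))
  expect_true(all(diff(bis) >= 0))
})

test_that("feature extraction reports one row per fitted unit and explains
           exclusions", {
  pop <- simulate_population(ca1_like_subtypes, duration = 600, seed = 41)
  fm <- extract_features(pop$set)
  expect_equal(nrow(fm), 60L)
  expect_true(all(c("unit_id", "k", "theta", "cv", "burst_index",
                    "mean_rate", "n_isi") %in% names(fm)))
  expect_true(all(fm$n_isi > 250))

  sparse <- spike_train_set(list(
    spike_train("few", cumsum(rexp(50, 2))),
    spike_train("many", cumsum(rexp(2000, 2)))), "s")
  fm2 <- extract_features(sparse)
  expect_equal(fm2$unit_id, "many")
  excl <- attr(fm2, "excluded")
  expect_equal(excl$unit_id, "few")
  expect_match(excl$reason, "n_isi <= 250")

  only_sparse <- spike_train_set(list(spike_train("few", c(1, 2, 3))), "s")
  expect_error(extract_features(only_sparse), "no unit passed")
})

test_that("half-split estimates of a stationary train agree across a
           population", {
  pop <- simulate_population(ca1_like_subtypes, duration = 1800, seed = 42)
  eps <- epoch_set(c(0, 900), c(900, 1800), c("h1", "h2"))
  f1 <- extract_features(pop$set, eps, "h1")
  f2 <- extract_features(pop$set, eps, "h2")
  common <- intersect(f1$unit_id, f2$unit_id)
  expect_gte(length(common), 55L)
  k1 <- f1$k[match(common, f1$unit_id)]
  k2 <- f2$k[match(common, f2$unit_id)]
  expect_gt(cor(k1, k2), 0.9)
})

test_that("k and cv are uncorrelated with mean rate when shape is fixed", {
  subtypes <- list(list(name = "a", n_units = 100, k_range = c(1.0, 1.0),
                        rate_range = c(0.5, 8), process = "gamma"))
  pop <- simulate_population(subtypes, duration = 1500, seed = 43)
  fm <- extract_features(pop$set)
  expect_lt(abs(cor(fm$k, fm$mean_rate)), 0.2)
  expect_lt(abs(cor(fm$cv, fm$mean_rate)), 0.2)
})
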