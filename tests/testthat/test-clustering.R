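test_that("cosine distance follows its definition", {
  expect_equal(cosine_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(c(2, 0), c(-3, 0)), 2)
  u <- c(1, 1); v <- c(2, 2.1)
  expect_equal(cosine_distance(u, v),
               1 - sum(u * v) / (sqrt(2) * sqrt(4 + 2.1^2)))
  expect_equal(cosine_distance(c(1, 2), c(3, 6)), 0, tolerance = 1e-12)
  expect_error(cosine_distance(c(0, 0), c(1, 1)), "zero vector")
})

test_that("k-means degenerate cases behave", {
  X <- make_two_cluster(2)
  f1 <- kmeans_cosine(X, 1, columns = NULL)
  expect_equal(f1$centroids[1, ], colMeans(X), ignore_attr = TRUE)
  fn <- kmeans_cosine(X[1:6, ], 6, n_restarts = 50, seed = 1, columns = NULL)
  expect_equal(fn$distortion, 0, tolerance = 1e-12)
  expect_error(kmeans_cosine(X[1:3, ], 5, columns = NULL), "exceeds")
  expect_error(kmeans_cosine(rbind(c(0, 0), c(1, 1)), 2, columns = NULL),
               "non-zero")
})

test_that("restarted k-means attains the exhaustive-assignment optimum on
           small instances", {
  set.seed(51)
  for (rep in 1:6) {
    ang <- c(runif(4, 0.1, 0.5), runif(4, 0.9, 1.4))
    rad <- runif(8, 0.5, 2)
    X <- cbind(rad * cos(ang), rad * sin(ang))
    opt <- exhaustive_sq_cosine_optimum(X, 2)
    fit <- kmeans_cosine(X, 2, n_restarts = 200, seed = rep, columns = NULL)
    expect_equal(fit$distortion, opt, tolerance = 1e-12)
  }
  # unstructured points as well
  for (rep in 1:4) {
    X <- matrix(runif(16, 0.2, 2), 8, 2)
    opt <- exhaustive_sq_cosine_optimum(X, 2)
    fit <- kmeans_cosine(X, 2, n_restarts = 300, seed = 100 + rep,
                         columns = NULL)
    expect_equal(fit$distortion, opt, tolerance = 1e-12)
  }
})

test_that("angularly separated clouds are recovered exactly and centroids
           are member means", {
  X <- make_two_cluster(3)
  fit <- kmeans_cosine(X, 2, n_restarts = 200, seed = 5, columns = NULL)
  expect_true(memberships_agree(fit$labels, two_cluster_truth))
  for (k in 1:2)
    expect_equal(fit$centroids[k, ],
                 colMeans(X[fit$labels == k, , drop = FALSE]),
                 ignore_attr = TRUE)
})

test_that("jump selection recovers 1, 2 and 3 clusters and its curve is
           coherent", {
  r2 <- jump_select_k(make_two_cluster(7), k_max = 8, n_restarts = 200,
                      seed = 7, columns = NULL)
  expect_equal(r2$selected_K, 2L)
  expect_equal(r2$selected_K, which.max(r2$jumps))
  expect_true(all(diff(r2$distortion_by_K) <= 1e-12))

  r1 <- jump_select_k(make_single_gaussian(7), k_max = 8, n_restarts = 200,
                      seed = 8, columns = NULL)
  expect_equal(r1$selected_K, 1L)

  r3 <- jump_select_k(make_three_cluster(7), k_max = 8, n_restarts = 200,
                      seed = 9, columns = NULL)
  expect_equal(r3$selected_K, 3L)
})

test_that("clustering is invariant to row order up to label permutation", {
  X <- make_two_cluster(10)
  set.seed(60)
  perm <- sample(nrow(X))
  f1 <- jump_select_k(X, k_max = 6, n_restarts = 200, seed = 11,
                      columns = NULL)
  f2 <- jump_select_k(X[perm, ], k_max = 6, n_restarts = 200, seed = 12,
                      columns = NULL)
  expect_equal(f2$selected_K, f1$selected_K)
  expect_true(memberships_agree(f1$labels[perm], f2$labels))
})

test_that("half-session clusterings of stationary recordings agree for
           every unit", {
  pop <- simulate_population(ca1_like_subtypes, duration = 1800, seed = 61)
  eps <- epoch_set(c(0, 900), c(900, 1800), c("h1", "h2"))
  f1 <- extract_features(pop$set, eps, "h1")
  f2 <- extract_features(pop$set, eps, "h2")
  common <- intersect(f1$unit_id, f2$unit_id)
  # renewal features are coupled (cv = 1/sqrt(k)): effective within-cluster
  # dimension 1, so the jump transform uses Y = p_eff / 2 = 0.5
  c1 <- jump_select_k(f1[match(common, f1$unit_id), ], k_max = 6, Y = 0.5,
                      n_restarts = 200, seed = 13)
  c2 <- jump_select_k(f2[match(common, f2$unit_id), ], k_max = 6, Y = 0.5,
                      n_restarts = 200, seed = 14)
  expect_equal(c1$selected_K, 2L)
  expect_equal(c2$selected_K, 2L)
  expect_true(memberships_agree(c1$labels, c2$labels))
})

test_that("hierarchical separation distinguishes real from random labels", {
  X <- make_two_cluster(15)
  good <- hierarchical_separation(X, two_cluster_truth, columns = NULL)
  expect_lt(good$p_value, 0.001)
  expect_gt(good$t_statistic, 0)

  X1 <- make_single_gaussian(15)
  set.seed(15)
  rand_lab <- sample(1:2, nrow(X1), replace = TRUE)
  bad <- hierarchical_separation(X1, rand_lab, columns = NULL)
  expect_gt(bad$p_value, 0.05)

  dup <- rbind(c(1, 1), c(1, 1), c(2, 1), c(2.1, 1))
  rep_l <- c(1, 1, 2, 2)
  r <- hierarchical_separation(dup, rep_l, columns = NULL)
  expect_equal(min(r$intra), 0)
  expect_error(hierarchical_separation(X, rep(1, nrow(X)), columns = NULL),
               "at least 2")
})
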