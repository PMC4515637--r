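# Shared fixtures and independent oracles. Everything is generated in code;
# nothing is read from disk.

# Two-cluster (k, cv) fixture matching the reported CA1 subtype means and
# SEM-implied spreads (sd = SEM * sqrt(n)): 36 units at (0.460, 1.705) and
# 34 units at (0.983, 1.100).
make_two_cluster <- function(seed) {
  set.seed(seed)
  A <- cbind(rnorm(36, 0.460, 0.013 * sqrt(36)),
             rnorm(36, 1.705, 0.046 * sqrt(36)))
  B <- cbind(rnorm(34, 0.983, 0.027 * sqrt(34)),
             rnorm(34, 1.100, 0.030 * sqrt(34)))
  X <- rbind(A, B)
  X[X <= 0.01] <- 0.01  # keep the quadrant positive
  colnames(X) <- c("k", "cv")
  X
}

two_cluster_truth <- rep(1:2, c(36, 34))

make_single_gaussian <- function(seed, n = 70) {
  set.seed(seed)
  X <- cbind(rnorm(n, 0.7, 0.15), rnorm(n, 1.4, 0.25))
  X[X <= 0.01] <- 0.01
  colnames(X) <- c("k", "cv")
  X
}

make_three_cluster <- function(seed) {
  set.seed(seed)
  X <- rbind(cbind(rnorm(25, 1, 0.05), rnorm(25, 0.2, 0.02)),
             cbind(rnorm(25, 1, 0.05), rnorm(25, 1, 0.05)),
             cbind(rnorm(25, 0.2, 0.02), rnorm(25, 1, 0.05)))
  colnames(X) <- c("k", "cv")
  X
}

# CA1-like two-subtype gamma-renewal population: shape centers at the
# reported subtype means, rates in the low pyramidal range. Ranges are kept
# narrow so each subtype forms one coherent cluster: renewal features are
# coupled (cv = 1/sqrt(k)), so all within-subtype spread lies along one
# curve, and the total within-cluster dispersion (parameter spread plus
# estimation noise) stays of the same order as the reported cluster SDs.
# Because of that coupling the features of such populations are effectively
# one-dimensional within clusters, and jump selection on them uses
# Y = 1/2 (= p_eff / 2).
ca1_like_subtypes <- list(
  list(name = "low_k", n_units = 30, k_range = c(0.44, 0.50),
       rate_range = c(2, 4), process = "gamma"),
  list(name = "high_k", n_units = 30, k_range = c(0.93, 1.05),
       rate_range = c(2, 4), process = "gamma")
)

# --- independent oracles -------------------------------------------------

# profile-likelihood grid search for the gamma shape (theta = mean/k);
# a coarse pass then a refined pass around the coarse maximizer
grid_gamma_fit <- function(isis, k_lo = 0.05, k_hi = 20, n_grid = 2000) {
  m <- mean(isis)
  ll_at <- function(k) sum(dgamma(isis, shape = k, scale = m / k, log = TRUE))
  ks <- exp(seq(log(k_lo), log(k_hi), length.out = n_grid))
  ll <- vapply(ks, ll_at, numeric(1))
  i <- which.max(ll)
  ks2 <- seq(ks[max(1, i - 1)], ks[min(n_grid, i + 1)], length.out = 2000)
  ll2 <- vapply(ks2, ll_at, numeric(1))
  list(k = ks2[which.max(ll2)], loglik = max(ll2))
}

cosd <- function(u, v) 1 - sum(u * v) / sqrt(sum(u^2) * sum(v^2))

# exhaustive-assignment optimum of the mean squared cosine distortion with
# mean centroids (feasible for n <= 8)
exhaustive_sq_cosine_optimum <- function(X, K) {
  n <- nrow(X)
  stopifnot(n <= 8)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    a <- grid[r, ]
    if (length(unique(a)) < K) next
    d <- 0
    for (k in seq_len(K)) {
      c0 <- colMeans(X[a == k, , drop = FALSE])
      if (all(c0 == 0)) { d <- Inf; break }
      d <- d + sum(vapply(which(a == k), function(i) cosd(X[i, ], c0)^2,
                          numeric(1)))
    }
    best <- min(best, d / n)
  }
  best
}

# membership agreement up to label permutation (two-cluster case)
memberships_agree <- function(a, b) {
  max(mean(a == b), mean(a == (3L - b))) == 1
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
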