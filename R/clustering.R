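# Stages 3-4: cosine-distance k-means with many random restarts, the
# distortion curve over K, jump-method selection of the cluster count, and a
# hierarchical intra- vs inter-cluster separation check.

#' Cosine distance between two feature vectors
#'
#' One minus the cosine of the angle between the vectors. Zero iff the
#' vectors are positive scalar multiples of each other; ranges over
#' `[0, 2]`.
#'
#' @param u,v non-zero numeric vectors of equal length.
#' @return the cosine distance.
#' @export
cosine_distance <- function(u, v) {
  u <- as.double(u); v <- as.double(v)
  if (length(u) != length(v)) stop("vectors differ in length", call. = FALSE)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("cosine distance undefined for a zero vector", call. = FALSE)
  1 - sum(u * v) / (nu * nv)
}

# full pairwise cosine-distance matrix
cosine_distance_matrix <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  if (any(nrm == 0))
    stop("cosine distance undefined for a zero vector", call. = FALSE)
  S <- (M / nrm) %*% t(M / nrm)
  D <- 1 - S
  D[D < 0] <- 0  # clip fp noise on the diagonal
  D
}

#' Cosine-distance k-means with random restarts
#'
#' Lloyd's algorithm under the cosine distance: points are assigned to the
#' angularly nearest centroid and each centroid is the arithmetic mean of
#' its members. Because the partition depends on the starting centroids, the
#' algorithm is restarted `n_restarts` times from random data points and the
#' solution with the smallest distortion — the mean squared cosine distance
#' of points to their assigned centroid — is returned. Empty clusters are
#' re-seeded at the point farthest from its centroid.
#'
#' @param X feature table (data frame with `k`, `cv` columns) or numeric
#'   matrix with one unit per row; rows must be non-zero vectors.
#' @param K number of clusters, `1 <= K <= nrow(X)`.
#' @param n_restarts number of random restarts (default 10000, the full
#'   budget; reduce for exploratory work).
#' @param seed integer seed or `NULL`.
#' @param columns feature columns used when `X` is a data frame.
#' @param init optional `K x p` matrix of centroids tried as one extra
#'   (deterministic) restart.
#' @param max_iter Lloyd iteration cap per restart.
#' @param distortion how candidate solutions are scored across restarts and
#'   reported: `"sq_cosine"` (default) is the mean squared cosine distance
#'   of points to their assigned centroid; `"std_euclidean"` is the mean
#'   squared Euclidean distance per dimension on column-standardized
#'   features (the within-cluster dispersion the jump method transforms).
#' @return list with `labels` (1..K per row), `centroids` (`K x p`),
#'   `distortion`, `K`, `n_restarts`, `distortion_type`.
#' @export
kmeans_cosine <- function(X, K, n_restarts = 10000L, seed = NULL,
                          columns = c("k", "cv"), init = NULL,
                          max_iter = 100L,
                          distortion = c("sq_cosine", "std_euclidean")) {
  M <- as_feature_matrix(X, columns = columns)
  distortion <- match.arg(distortion)
  n <- nrow(M)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (K > n) stop("K = ", K, " exceeds the number of units (", n, ")",
                  call. = FALSE)
  score <- if (distortion == "std_euclidean") standardize_columns(M) else NULL
  if (K == 1L) {
    cen <- matrix(colMeans(M), nrow = 1L,
                  dimnames = list(NULL, colnames(M)))
    d1 <- if (is.null(score)) {
      mean(vapply(seq_len(n), function(i)
        cosine_distance(M[i, ], cen[1L, ])^2, numeric(1L)))
    } else {
      mean(sweep(score, 2L, colMeans(score))^2)
    }
    return(list(labels = rep.int(1L, n), centroids = cen,
                distortion = d1, K = 1L, n_restarts = 0L,
                distortion_type = distortion))
  }
  res <- with_seed(seed,
                   cpp_kmeans_cosine(M, as.integer(K),
                                     as.integer(n_restarts), init,
                                     as.integer(max_iter), score))
  colnames(res$centroids) <- colnames(M)
  res$K <- as.integer(K)
  res$n_restarts <- as.integer(n_restarts)
  res$distortion_type <- distortion
  res
}

# z-score columns; constant columns are left centered at 0
standardize_columns <- function(M) {
  mu <- colMeans(M)
  sd <- apply(M, 2L, stats::sd)
  sd[sd == 0] <- 1
  sweep(sweep(M, 2L, mu), 2L, sd, "/")
}

#' Select the number of clusters by the jump method
#'
#' Runs restarted cosine k-means for `K = 1..k_max`, records the distortion
#' `d_K` of the best solution at each K, transforms the non-increasing
#' distortion curve by the negative power `Y` (`t_K = d_K^-Y`), and selects
#' the K with the largest jump `J_K = t_K - t_{K-1}` (with `t_0 := 0`, so
#' `K = 1` is selectable). The transformed distortion rises sharply at the
#' true cluster count and flattens beyond it. Ties break toward smaller K;
#' a zero distortion (exact duplicates) makes the first K reaching it the
#' selected one.
#'
#' The distortion fed to the transform is, by default, the jump method's
#' own within-cluster dispersion — mean squared Euclidean distance per
#' dimension on column-standardized features (a diagonal-covariance
#' Mahalanobis distance) — measured on the partitions produced by cosine
#' k-means, with the best restart at each K chosen by that same quantity.
#' `distortion = "sq_cosine"` instead transforms the squared-cosine
#' distortion; note that the cosine metric collapses the features onto the
#' unit sphere (effective dimension p - 1), which makes its distortion
#' decay much faster in K, so a correspondingly smaller `Y` is needed and
#' selection is less stable on small samples.
#'
#' @param X feature table or matrix (one unit per row).
#' @param k_max largest K examined; must not exceed `nrow(X)`.
#' @param Y transform power; defaults to half the feature dimensionality
#'   (`p/2`), the jump method's standard choice.
#' @param n_restarts restarts per K.
#' @param seed integer seed or `NULL`.
#' @param columns feature columns used when `X` is a data frame.
#' @param distortion distortion definition, see Details.
#' @return object of class `isica_clustering`: list with `labels`,
#'   `centroids`, `selected_K`, `distortion_by_K`, `transformed`, `jumps`,
#'   `Y`, `n_restarts`, `seed`, plus `models` (per-K k-means results).
#' @export
jump_select_k <- function(X, k_max = 8L, Y = NULL, n_restarts = 10000L,
                          seed = NULL, columns = c("k", "cv"),
                          distortion = c("std_euclidean", "sq_cosine")) {
  distortion <- match.arg(distortion)
  M <- as_feature_matrix(X, columns = columns)
  n <- nrow(M)
  if (k_max > n)
    stop("k_max = ", k_max, " exceeds the number of units (", n, ")",
         call. = FALSE)
  Y <- Y %||% (ncol(M) / 2)
  models <- vector("list", k_max)
  dist_k <- numeric(k_max)
  prev_cent <- NULL
  for (K in seq_len(k_max)) {
    init <- NULL
    if (!is.null(prev_cent)) {
      # warm start: previous best centroids plus the worst-fit point
      prev_fit <- models[[K - 1L]]
      dd <- vapply(seq_len(n), function(i)
        cosine_distance(M[i, ], prev_cent[prev_fit$labels[i], ]), numeric(1L))
      init <- rbind(prev_cent, M[which.max(dd), , drop = FALSE])
    }
    fit <- kmeans_cosine(M, K, n_restarts = n_restarts,
                         seed = if (is.null(seed)) NULL else
                           derive_seed(seed, K),
                         init = init, distortion = distortion)
    models[[K]] <- fit
    dist_k[K] <- fit$distortion
    prev_cent <- fit$centroids
  }
  transformed <- ifelse(dist_k > 0, dist_k^(-Y), Inf)
  jumps <- transformed - c(0, transformed[-k_max])
  jumps[!is.finite(transformed) & c(FALSE, !is.finite(transformed[-k_max]))] <- -Inf
  selected <- which.max(jumps)  # first max: ties break toward smaller K
  best <- models[[selected]]
  structure(list(labels = best$labels, centroids = best$centroids,
                 selected_K = as.integer(selected),
                 distortion_by_K = dist_k, transformed = transformed,
                 jumps = jumps, Y = Y, n_restarts = n_restarts, seed = seed,
                 distortion_type = distortion, models = models),
            class = "isica_clustering")
}

#' @export
print.isica_clustering <- function(x, ...) {
  cat(sprintf("<isica clustering: selected K = %d (Y = %g, %d restarts)>\n",
              x$selected_K, x$Y, x$n_restarts))
  cat("distortion by K:", format(signif(x$distortion_by_K, 4)), "\n")
  invisible(x)
}

#' Hierarchical separation check of a clustering
#'
#' Partitions all pairwise cosine distances into intra-cluster and
#' inter-cluster sets and tests (two-sample t-test) whether inter-cluster
#' distances exceed intra-cluster distances. Singleton clusters contribute
#' no intra-cluster pairs and are flagged with a warning. An average-linkage
#' hierarchical tree on the same distances is attached for inspection.
#'
#' @param X feature table or matrix.
#' @param labels integer cluster labels (>= 2 clusters).
#' @param columns feature columns used when `X` is a data frame.
#' @return list with `intra`, `inter` (distance summaries), `t_statistic`,
#'   `p_value`, `hclust`.
#' @export
hierarchical_separation <- function(X, labels, columns = c("k", "cv")) {
  M <- as_feature_matrix(X, columns = columns)
  labels <- as.integer(labels)
  if (length(labels) != nrow(M))
    stop("labels length must match rows of X", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("separation check needs at least 2 clusters", call. = FALSE)
  sizes <- table(labels)
  if (any(sizes < 2L))
    warning("singleton cluster(s) contribute no intra-cluster distances")
  D <- cosine_distance_matrix(M)
  iu <- which(upper.tri(D), arr.ind = TRUE)
  same <- labels[iu[, 1L]] == labels[iu[, 2L]]
  intra <- D[iu][same]; inter <- D[iu][!same]
  if (length(intra) < 2L || length(inter) < 2L)
    stop("too few pairwise distances for a separation test", call. = FALSE)
  tt <- stats::t.test(inter, intra, alternative = "greater")
  list(intra = summary(intra), inter = summary(inter),
       n_intra = length(intra), n_inter = length(inter),
       t_statistic = unname(tt$statistic), p_value = tt$p.value,
       hclust = stats::hclust(stats::as.dist(D), method = "average"))
}
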