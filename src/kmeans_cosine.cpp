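// Restarted Lloyd k-means under the cosine distance
// d(u, v) = 1 - u.v / (|u||v|), with centroids taken as arithmetic means of
// cluster members. The reported solution is the best (labels, mean-centroid)
// pair seen across all iterations of all restarts, scored by the mean
// squared cosine distance of points to their assigned centroid (the
// "distortion" fed to the jump method). Initial centroids are K distinct
// data points drawn with R's RNG so results are reproducible via set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline double dot_cols(const double* X, int n, int d, int i,
                              const std::vector<double>& c) {
  double s = 0.0;
  for (int j = 0; j < d; ++j) s += X[i + (size_t)j * n] * c[j];
  return s;
}

// When `score` (an n x d matrix, typically the column-standardized data) is
// supplied, candidate solutions are ranked by the mean squared Euclidean
// distance per dimension of score-rows to their cluster means — the
// distortion the jump method transforms — instead of by the squared cosine
// distortion. The Lloyd dynamics themselves always use the cosine metric.

// [[Rcpp::export]]
List cpp_kmeans_cosine(NumericMatrix X, int K, int n_restarts,
                       Nullable<NumericMatrix> init, int max_iter,
                       Nullable<NumericMatrix> score) {
  const int n = X.nrow(), d = X.ncol();
  const double* x = REAL(X);

  bool use_score = score.isNotNull();
  NumericMatrix score_m;
  const double* z = nullptr;
  if (use_score) {
    score_m = NumericMatrix(score);
    if (score_m.nrow() != n || score_m.ncol() != d)
      stop("score matrix must have the same shape as X");
    z = REAL(score_m);
  }

  std::vector<double> xnorm(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) {
      double v = x[i + (size_t)j * n];
      s += v * v;
    }
    xnorm[i] = std::sqrt(s);
    if (xnorm[i] <= 0.0)
      stop("cosine k-means requires non-zero feature vectors (row %d)", i + 1);
  }

  double best_dist = std::numeric_limits<double>::infinity();
  std::vector<int> best_lab(n, 0);
  std::vector<double> best_cent((size_t)K * d, 0.0);

  std::vector<int> lab(n), prev(n);
  std::vector<double> cent((size_t)K * d), cnorm(K);
  std::vector<int> cnt(K);
  std::vector<int> pick(K);

  bool have_init = init.isNotNull();
  NumericMatrix init_m;
  if (have_init) {
    init_m = NumericMatrix(init);
    if (init_m.nrow() != K || init_m.ncol() != d)
      stop("init centroid matrix must be K x d");
  }
  const int total = n_restarts + (have_init ? 1 : 0);

  for (int r = 0; r < total; ++r) {
    // --- initial centroids ---
    if (have_init && r == 0) {
      for (int k = 0; k < K; ++k)
        for (int j = 0; j < d; ++j)
          cent[k + (size_t)j * K] = init_m(k, j);
    } else {
      for (int k = 0; k < K; ++k) {
        int idx;
        bool dup;
        int guard = 0;
        do {
          idx = (int)(unif_rand() * n);
          if (idx >= n) idx = n - 1;
          dup = false;
          for (int q = 0; q < k; ++q) if (pick[q] == idx) { dup = true; break; }
        } while (dup && ++guard < 1000);
        pick[k] = idx;
        for (int j = 0; j < d; ++j)
          cent[k + (size_t)j * K] = x[idx + (size_t)j * n];
      }
    }
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < d; ++j) {
        double v = cent[k + (size_t)j * K];
        s += v * v;
      }
      cnorm[k] = std::sqrt(s);
    }
    std::fill(prev.begin(), prev.end(), -1);

    for (int iter = 0; iter < max_iter; ++iter) {
      // --- assignment: maximize cosine similarity ---
      for (int i = 0; i < n; ++i) {
        double best = -std::numeric_limits<double>::infinity();
        int bk = 0;
        for (int k = 0; k < K; ++k) {
          if (cnorm[k] <= 0.0) continue;
          double s = 0.0;
          for (int j = 0; j < d; ++j)
            s += x[i + (size_t)j * n] * cent[k + (size_t)j * K];
          s /= cnorm[k];
          if (s > best) { best = s; bk = k; }
        }
        lab[i] = bk;
      }

      bool same = true;
      for (int i = 0; i < n; ++i) if (lab[i] != prev[i]) { same = false; break; }
      if (same) break;

      // --- repair empty clusters: move the worst-fit point there ---
      std::fill(cnt.begin(), cnt.end(), 0);
      for (int i = 0; i < n; ++i) ++cnt[lab[i]];
      for (int k = 0; k < K; ++k) {
        if (cnt[k] > 0) continue;
        double worst = -1.0; int wi = 0;
        for (int i = 0; i < n; ++i) {
          if (cnt[lab[i]] <= 1) continue;
          int a = lab[i];
          if (cnorm[a] <= 0.0) { wi = i; worst = 2.0; break; }
          std::vector<double> cv(d);
          for (int j = 0; j < d; ++j) cv[j] = cent[a + (size_t)j * K];
          double dd = 1.0 - dot_cols(x, n, d, i, cv) / (xnorm[i] * cnorm[a]);
          if (dd > worst) { worst = dd; wi = i; }
        }
        --cnt[lab[wi]];
        lab[wi] = k;
        cnt[k] = 1;
      }

      // --- update: centroids = member means ---
      std::fill(cent.begin(), cent.end(), 0.0);
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < d; ++j)
          cent[lab[i] + (size_t)j * K] += x[i + (size_t)j * n];
      bool degenerate = false;
      for (int k = 0; k < K; ++k) {
        double s = 0.0;
        for (int j = 0; j < d; ++j) {
          cent[k + (size_t)j * K] /= cnt[k];
          double v = cent[k + (size_t)j * K];
          s += v * v;
        }
        cnorm[k] = std::sqrt(s);
        if (cnorm[k] <= 1e-300) degenerate = true;
      }

      // --- score the (labels, mean-centroid) candidate ---
      if (!degenerate) {
        double dist = 0.0;
        if (use_score) {
          // mean squared Euclidean distance per dimension on the score rows
          std::vector<double> zc((size_t)K * d, 0.0);
          for (int i = 0; i < n; ++i)
            for (int j = 0; j < d; ++j)
              zc[lab[i] + (size_t)j * K] += z[i + (size_t)j * n];
          for (int k = 0; k < K; ++k)
            for (int j = 0; j < d; ++j)
              zc[k + (size_t)j * K] /= cnt[k];
          for (int i = 0; i < n; ++i)
            for (int j = 0; j < d; ++j) {
              double dd = z[i + (size_t)j * n] - zc[lab[i] + (size_t)j * K];
              dist += dd * dd;
            }
          dist /= (double)n * d;
        } else {
          for (int i = 0; i < n; ++i) {
            int a = lab[i];
            double s = 0.0;
            for (int j = 0; j < d; ++j)
              s += x[i + (size_t)j * n] * cent[a + (size_t)j * K];
            double dd = 1.0 - s / (xnorm[i] * cnorm[a]);
            dist += dd * dd;
          }
          dist /= n;
        }
        if (dist < best_dist) {
          best_dist = dist;
          best_lab = lab;
          best_cent = cent;
        }
      }
      prev = lab;
    }
  }

  IntegerVector labels(n);
  for (int i = 0; i < n; ++i) labels[i] = best_lab[i] + 1;
  NumericMatrix centroids(K, d);
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < d; ++j)
      centroids(k, j) = best_cent[k + (size_t)j * K];
  return List::create(_["labels"] = labels,
                      _["centroids"] = centroids,
                      _["distortion"] = best_dist);
}
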