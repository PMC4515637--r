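# Stage 2: pre-clustering screen — D'Agostino–Pearson omnibus normality test
# per feature. Rejection of normality is the evidence that sub-populations
# are plausible before any clustering is attempted.

#' D'Agostino–Pearson omnibus normality test
#'
#' Combines the standardized skewness test (D'Agostino 1970) and the
#' standardized kurtosis test (Anscombe–Glynn 1983) into
#' `K2 = Z_skew^2 + Z_kurt^2`, referred to a chi-square distribution with
#' 2 degrees of freedom. Requires `n >= 20`, below which the kurtosis
#' normalization is unreliable. The decision is invariant to affine
#' rescaling of the data.
#'
#' @param values numeric vector, `n >= 20`, non-constant.
#' @param alpha rejection level.
#' @param feature optional name carried into the report.
#' @return list with `feature`, `n`, `K2`, `z_skew`, `z_kurt`, `p_value`,
#'   and `decision` (`"multimodal-candidate"` when `p < alpha`, else
#'   `"unimodal-consistent"`).
#' @export
dagostino_pearson <- function(values, alpha = 0.05, feature = NA_character_) {
  values <- as.double(values)
  n <- length(values)
  if (n < 20L)
    stop("D'Agostino-Pearson test requires n >= 20 (got ", n, ")",
         call. = FALSE)
  if (stats::var(values) == 0)
    stop("normality test undefined for a constant (zero-variance) feature",
         call. = FALSE)
  x <- values - mean(values)
  m2 <- mean(x^2); m3 <- mean(x^3); m4 <- mean(x^4)

  # skewness: D'Agostino's Z via Johnson SU transform
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha_s <- sqrt(2 / (w2 - 1))
  z_skew <- delta * log(y / alpha_s + sqrt((y / alpha_s)^2 + 1))

  # kurtosis: Anscombe-Glynn Z
  b2 <- m4 / m2^2
  e_b2 <- 3 * (n - 1) / (n + 1)
  var_b2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - e_b2) / sqrt(var_b2)
  sqrt_b1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrt_b1 * (2 / sqrt_b1 + sqrt(1 + 4 / sqrt_b1^2))
  term <- (1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4)))
  cbrt <- sign(term) * abs(term)^(1 / 3)   # signed cube root (term can be < 0)
  z_kurt <- ((1 - 2 / (9 * a)) - cbrt) / sqrt(2 / (9 * a))

  k2 <- z_skew^2 + z_kurt^2
  p <- stats::pchisq(k2, df = 2, lower.tail = FALSE)
  list(feature = feature, n = n, K2 = k2, z_skew = z_skew, z_kurt = z_kurt,
       p_value = p,
       decision = if (p < alpha) "multimodal-candidate" else
         "unimodal-consistent")
}

#' Screen the clustered features for departures from normality
#'
#' Runs [dagostino_pearson()] on each feature column and sets
#' `proceed = TRUE` when any column rejects normality at `alpha` — the
#' pre-clustering evidence that more than one sub-population may be present.
#' A non-rejection is reported as "normality not rejected"; it is evidence,
#' not a hard stop, and clustering can be forced downstream.
#'
#' @param fm feature table (data frame from [extract_features()]) or matrix.
#' @param alpha rejection level.
#' @param features columns to screen (default `k` and `cv`).
#' @return list with `reports` (data frame: feature, n, K2, p_value,
#'   decision) and `proceed` (logical).
#' @export
screen_features <- function(fm, alpha = 0.05, features = c("k", "cv")) {
  M <- as_feature_matrix(fm, columns = features)
  if (nrow(M) < 20L)
    stop("screening requires at least 20 units", call. = FALSE)
  reports <- do.call(rbind, lapply(seq_len(ncol(M)), function(j) {
    r <- dagostino_pearson(M[, j], alpha = alpha, feature = colnames(M)[j])
    data.frame(feature = r$feature, n = r$n, K2 = r$K2, p_value = r$p_value,
               decision = r$decision, stringsAsFactors = FALSE)
  }))
  list(reports = reports, proceed = any(reports$p_value < alpha))
}
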