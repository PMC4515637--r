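# Unit-quality metrics (Isolation Distance, L-ratio), quality filtering, and
# rule-based putative cell-type assignment.

mahal_sq <- function(P, mu, S_inv) {
  D <- sweep(P, 2L, mu)
  rowSums((D %*% S_inv) * D)
}

check_quality_inputs <- function(cluster_features, noise_features) {
  C <- as.matrix(cluster_features); N <- as.matrix(noise_features)
  if (ncol(C) != ncol(N))
    stop("cluster and noise features must share dimensionality", call. = FALSE)
  S <- stats::cov(C)
  S_inv <- tryCatch(solve(S), error = function(e)
    stop("singular cluster covariance: metric undefined", call. = FALSE))
  list(C = C, N = N, mu = colMeans(C), S_inv = S_inv)
}

#' Isolation Distance of a sorted unit
#'
#' Squared Mahalanobis distance — with respect to the cluster's mean and
#' covariance — of the `n_c`-th nearest noise (non-cluster) spike, where
#' `n_c` is the cluster size. Larger values mean better isolation; undefined
#' (returned as `NA` with a warning) when fewer noise spikes than cluster
#' spikes exist.
#'
#' @param cluster_features `n_c x d` matrix of the unit's spike features.
#' @param noise_features `n_o x d` matrix of all other spikes' features.
#' @return the Isolation Distance (or `NA` if undefined).
#' @export
isolation_distance <- function(cluster_features, noise_features) {
  q <- check_quality_inputs(cluster_features, noise_features)
  n_c <- nrow(q$C)
  if (nrow(q$N) < n_c) {
    warning("Isolation Distance undefined: fewer noise spikes than cluster spikes")
    return(NA_real_)
  }
  d2 <- mahal_sq(q$N, q$mu, q$S_inv)
  sort(d2, partial = n_c)[n_c]
}

#' L-ratio of a sorted unit
#'
#' Sum over noise spikes of the chi-square upper-tail probability (df = the
#' feature dimensionality) of their squared Mahalanobis distance to the
#' cluster, divided by the cluster size. Near 0 for well-separated units.
#'
#' @inheritParams isolation_distance
#' @return the L-ratio.
#' @export
l_ratio <- function(cluster_features, noise_features) {
  q <- check_quality_inputs(cluster_features, noise_features)
  d2 <- mahal_sq(q$N, q$mu, q$S_inv)
  sum(stats::pchisq(d2, df = ncol(q$C), lower.tail = FALSE)) / nrow(q$C)
}

#' Filter units on isolation quality
#'
#' Keeps units with `isolation_distance > id_min` and `l_ratio < lr_max`
#' (strict inequalities, so boundary values are dropped). Units with a
#' missing metric are dropped with reason `"missing metric"`.
#'
#' @param units data frame with columns `unit_id`, `isolation_distance`,
#'   `l_ratio` (other columns pass through).
#' @param id_min minimum Isolation Distance (exclusive), default 15.
#' @param lr_max maximum L-ratio (exclusive), default 0.7.
#' @return list with `kept` and `dropped` data frames; `dropped` gains a
#'   `reason` column.
#' @export
quality_filter <- function(units, id_min = 15, lr_max = 0.7) {
  units <- as.data.frame(units)
  need <- c("unit_id", "isolation_distance", "l_ratio")
  if (!all(need %in% names(units)))
    stop("units table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  reason <- rep(NA_character_, nrow(units))
  miss <- is.na(units$isolation_distance) | is.na(units$l_ratio)
  reason[miss] <- "missing metric"
  low_id <- !miss & units$isolation_distance <= id_min
  high_lr <- !miss & units$l_ratio >= lr_max
  reason[low_id & high_lr] <- sprintf("isolation_distance <= %g and l_ratio >= %g",
                                      id_min, lr_max)
  reason[low_id & !high_lr] <- sprintf("isolation_distance <= %g", id_min)
  reason[!low_id & high_lr] <- sprintf("l_ratio >= %g", lr_max)
  keep <- is.na(reason)
  dropped <- units[!keep, , drop = FALSE]
  dropped$reason <- reason[!keep]
  list(kept = units[keep, , drop = FALSE], dropped = dropped)
}

#' Rule-based putative cell-type classification
#'
#' Pyramidal cells fire at low rates (< 5 Hz) with broad waveforms
#' (> 300 microseconds); interneurons fire at high rates (> 10 Hz) with
#' narrow waveforms (< 250 microseconds). Units matching neither rule are
#' `"unclassified"`.
#'
#' @param mean_rate firing rate(s) in Hz (> 0).
#' @param waveform_width waveform width(s) in microseconds (> 0).
#' @return character vector in `{"pyramidal", "interneuron", "unclassified"}`.
#' @export
classify_putative_type <- function(mean_rate, waveform_width) {
  if (length(mean_rate) != length(waveform_width))
    stop("inputs must have equal length", call. = FALSE)
  if (any(!is.finite(mean_rate)) || any(!is.finite(waveform_width)) ||
      any(mean_rate <= 0) || any(waveform_width <= 0))
    stop("mean_rate and waveform_width must be positive and finite",
         call. = FALSE)
  out <- rep("unclassified", length(mean_rate))
  out[mean_rate < 5 & waveform_width > 300] <- "pyramidal"
  out[mean_rate > 10 & waveform_width < 250] <- "interneuron"
  out
}
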