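# Stage 1: per-unit ISI features — gamma (k, theta) by maximum likelihood,
# coefficient of variation, burst index, mean rate.

#' Inter-spike intervals of a train
#'
#' Differences of consecutive spike times. When the train carries an
#' `isi_valid` attribute (set by [restrict_to_epochs()]) or an explicit
#' `mask` is given, ISIs flagged invalid — those straddling an epoch
#' boundary — are dropped, so renewal statistics never include artificial
#' gap intervals.
#'
#' @param train a [spike_train].
#' @param mask optional logical vector (length `n_spikes - 1`); `TRUE` keeps
#'   the ISI. Defaults to the train's `isi_valid` attribute, else all kept.
#' @return numeric vector of ISIs in seconds (empty if fewer than 2 spikes).
#' @export
compute_isis <- function(train, mask = NULL) {
  stopifnot(inherits(train, "spike_train"))
  n <- length(train$times)
  if (n < 2L) return(numeric(0L))
  isis <- diff(train$times)
  mask <- mask %||% attr(train, "isi_valid", exact = TRUE)
  if (!is.null(mask)) {
    if (length(mask) != length(isis))
      stop("mask length must equal n_spikes - 1", call. = FALSE)
    isis <- isis[mask]
  }
  isis
}

#' Coefficient of variation of ISIs
#'
#' `cv = sd(ISI) / mean(ISI)` with the sample (n-1) standard deviation. For a
#' Poisson process cv is 1; regular firing gives cv < 1, irregular firing
#' cv > 1. The value is invariant to rescaling all ISIs by a positive
#' constant.
#'
#' @param isis numeric vector of at least two positive ISIs.
#' @return the coefficient of variation (dimensionless).
#' @export
compute_cv <- function(isis) {
  if (length(isis) < 2L)
    stop("cv undefined: need at least 2 ISIs", call. = FALSE)
  m <- mean(isis)
  if (!is.finite(m) || m <= 0)
    stop("cv undefined: mean ISI must be positive", call. = FALSE)
  stats::sd(isis) / m
}

#' Maximum-likelihood gamma fit to ISIs
#'
#' Fits Gamma(shape `k`, scale `theta`) to raw ISIs. The shape solves the
#' profile-likelihood equation `log(k) - digamma(k) = log(mean) - mean(log)`
#' by Newton iteration from the method-of-moments start `k0 = mean^2 / var`;
#' then `theta = mean / k`. Units whose ISI count does not exceed `min_isi`
#' are not fitted (`fit_ok = FALSE`) to avoid under-sampling bias.
#'
#' @param isis numeric vector of positive ISIs.
#' @param min_isi fits require strictly more than this many ISIs
#'   (default 250).
#' @param tol Newton convergence tolerance on `k`.
#' @param max_iter Newton iteration cap.
#' @return list with `k`, `theta`, `loglik`, `fit_ok`, `n_isi`.
#' @export
fit_gamma_mle <- function(isis, min_isi = 250L, tol = 1e-10, max_iter = 200L) {
  n <- length(isis)
  if (n && any(isis <= 0))
    stop("all ISIs must be positive for a gamma fit", call. = FALSE)
  if (n <= min_isi)
    return(list(k = NA_real_, theta = NA_real_, loglik = NA_real_,
                fit_ok = FALSE, n_isi = n))
  v <- stats::var(isis)
  if (v == 0)
    stop("zero-variance ISIs: gamma shape is unbounded", call. = FALSE)
  m <- mean(isis)
  s <- log(m) - mean(log(isis))   # always > 0 by Jensen unless constant
  k <- m^2 / v                    # method-of-moments start
  for (i in seq_len(max_iter)) {
    f <- log(k) - digamma(k) - s
    fp <- 1 / k - trigamma(k)
    step <- f / fp
    k_new <- k - step
    if (k_new <= 0) k_new <- k / 2
    if (abs(k_new - k) < tol * max(1, k)) { k <- k_new; break }
    k <- k_new
  }
  theta <- m / k
  loglik <- sum(stats::dgamma(isis, shape = k, scale = theta, log = TRUE))
  list(k = k, theta = theta, loglik = loglik, fit_ok = TRUE, n_isi = n)
}

#' Burst index
#'
#' Fraction of ISIs strictly shorter than the burst threshold (10 ms by the
#' usual definition).
#'
#' @param isis numeric vector of ISIs (seconds), at least one.
#' @param threshold burst threshold in seconds.
#' @return fraction in `[0, 1]`.
#' @export
burst_index <- function(isis, threshold = 0.010) {
  if (!length(isis))
    stop("burst index undefined for an empty ISI vector", call. = FALSE)
  mean(isis < threshold)
}

#' Extract the per-unit feature table for one brain state
#'
#' For every unit: restrict to the state's epochs (when given), compute
#' ISIs (boundary-straddling ISIs excluded), and derive the gamma MLE
#' (k, theta), cv, burst index, mean rate and ISI count. Units that cannot
#' be fitted are excluded and reported with a reason in the `excluded`
#' attribute.
#'
#' @param set a [spike_train_set].
#' @param epochs optional [epoch_set]; with `label`, restricts each train.
#' @param label state label within `epochs`.
#' @param min_isi fit threshold passed to [fit_gamma_mle()].
#' @param burst_threshold seconds, passed to [burst_index()].
#' @return data frame with columns `unit_id`, `k`, `theta`, `cv`,
#'   `burst_index`, `mean_rate`, `n_isi`; attribute `excluded` is a data
#'   frame of dropped units and reasons.
#' @export
extract_features <- function(set, epochs = NULL, label = NULL,
                             min_isi = 250L, burst_threshold = 0.010) {
  stopifnot(inherits(set, "spike_train_set"))
  rows <- list(); dropped <- list()
  for (tr in set$trains) {
    if (!is.null(epochs)) {
      if (is.null(label))
        stop("`label` is required when `epochs` is given", call. = FALSE)
      tr <- restrict_to_epochs(tr, epochs, label)
    }
    isis <- compute_isis(tr)
    span <- attr(tr, "state_duration", exact = TRUE) %||%
      (if (length(tr$times) >= 2L) diff(range(tr$times)) else NA_real_)
    if (length(isis) < 2L) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(unit_id = tr$unit_id, reason = "fewer than 2 ISIs")
      next
    }
    if (stats::var(isis) == 0) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(unit_id = tr$unit_id, reason = "zero ISI variance")
      next
    }
    fit <- fit_gamma_mle(isis, min_isi = min_isi)
    if (!fit$fit_ok) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(unit_id = tr$unit_id,
                   reason = sprintf("n_isi <= %d", min_isi))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      unit_id = tr$unit_id,
      k = fit$k, theta = fit$theta,
      cv = compute_cv(isis),
      burst_index = burst_index(isis, threshold = burst_threshold),
      mean_rate = length(tr$times) / span,
      n_isi = fit$n_isi,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop("no unit passed feature extraction (all excluded)", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(unit_id = character(0L), reason = character(0L))
  out
}
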