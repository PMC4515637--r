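# LFP-based brain-state tools: theta/delta band-power ratio, slow-wave-sleep
# epoch detection, and normalized power-density spectra.

butter_bandpower <- function(x, fs, band, order = 4L) {
  ny <- fs / 2
  w <- band / ny
  if (any(w <= 0) || any(w >= 1))
    stop(sprintf("band (%g, %g) Hz not representable at fs = %g Hz",
                 band[1L], band[2L], fs), call. = FALSE)
  bf <- signal::butter(order, w, type = "pass")
  signal::filtfilt(bf, x)   # zero-phase
}

#' Windowed band-power ratio of an LFP signal
#'
#' Band-pass filters the signal (4th-order zero-phase Butterworth) in two
#' bands and reports, per sliding window, the ratio of mean squared
#' amplitude of `numerator` band to the other. Defaults follow the standard
#' theta (4-12 Hz) and delta (1-4 Hz) bands; the ratio is scale-free.
#'
#' @param lfp an [lfp_signal].
#' @param theta,delta band edges in Hz.
#' @param window,step window length and hop in seconds.
#' @param numerator `"theta"` (theta/delta, default) or `"delta"`
#'   (delta/theta, the direction that rises during slow-wave sleep).
#' @return data frame of class `band_ratio_series` with columns `t_start`,
#'   `t_end`, `center`, `ratio`.
#' @export
band_power_ratio <- function(lfp, theta = c(4, 12), delta = c(1, 4),
                             window = 2, step = 1,
                             numerator = c("theta", "delta")) {
  stopifnot(inherits(lfp, "lfp_signal"))
  numerator <- match.arg(numerator)
  if (lfp$fs <= 2 * max(theta, delta))
    stop("sampling rate too low for the requested bands", call. = FALSE)
  if (window < 1) stop("window must be at least 1 s", call. = FALSE)
  n <- length(lfp$samples)
  wlen <- round(window * lfp$fs)
  if (wlen > n) stop("window longer than the signal", call. = FALSE)
  xt <- butter_bandpower(lfp$samples, lfp$fs, theta)
  xd <- butter_bandpower(lfp$samples, lfp$fs, delta)
  starts <- seq(1L, n - wlen + 1L, by = max(1L, round(step * lfp$fs)))
  pt <- vapply(starts, function(s) mean(xt[s:(s + wlen - 1L)]^2), numeric(1L))
  pd <- vapply(starts, function(s) mean(xd[s:(s + wlen - 1L)]^2), numeric(1L))
  ratio <- if (numerator == "theta") pt / pd else pd / pt
  t_start <- lfp$t0 + (starts - 1L) / lfp$fs
  structure(data.frame(t_start = t_start, t_end = t_start + window,
                       center = t_start + window / 2, ratio = ratio),
            class = c("band_ratio_series", "data.frame"),
            numerator = numerator, window = window, step = step)
}

#' Detect slow-wave-sleep epochs from a band-power ratio series
#'
#' Windows whose ratio exceeds (or falls below) a threshold of
#' `center + multiplier * spread` are merged into contiguous epochs, and
#' epochs not longer than `min_duration` are discarded. SWS is
#' delta-dominant, so the intended usage is a delta/theta ratio (see
#' [band_power_ratio()] with `numerator = "delta"`) thresholded `"above"`.
#' Robust center/spread statistics (median and MAD) are the default so that
#' long SWS stretches do not inflate the threshold estimated from the
#' series itself; mean/SD are available for the classical criterion.
#'
#' @param ratio a `band_ratio_series`.
#' @param min_duration epochs must be strictly longer than this (seconds).
#' @param multiplier threshold multiplier on the spread statistic.
#' @param direction `"above"` or `"below"` the threshold.
#' @param center_stat `"median"` or `"mean"`.
#' @param spread_stat `"mad"` or `"sd"`.
#' @param label epoch label for the result.
#' @return an [epoch_set] (possibly empty).
#' @export
detect_sws <- function(ratio, min_duration = 5, multiplier = 5,
                       direction = c("above", "below"),
                       center_stat = c("median", "mean"),
                       spread_stat = c("mad", "sd"), label = "SWS") {
  stopifnot(inherits(ratio, "band_ratio_series"))
  direction <- match.arg(direction)
  center_stat <- match.arg(center_stat)
  spread_stat <- match.arg(spread_stat)
  if (!nrow(ratio)) stop("empty ratio series", call. = FALSE)
  r <- ratio$ratio
  ctr <- if (center_stat == "median") stats::median(r) else mean(r)
  spr <- if (spread_stat == "mad") stats::mad(r) else stats::sd(r)
  if (!is.finite(spr) || spr == 0) {
    warning("degenerate (constant) ratio series: no epochs detected")
    return(epoch_set())
  }
  thr <- if (direction == "above") ctr + multiplier * spr else
    ctr - multiplier * spr
  hit <- if (direction == "above") r > thr else r < thr
  if (!any(hit)) return(epoch_set())
  idx <- which(hit)
  run_start <- idx[c(TRUE, diff(idx) > 1L)]
  run_end <- idx[c(diff(idx) > 1L, TRUE)]
  starts <- ratio$t_start[run_start]
  ends <- ratio$t_end[run_end]
  keep <- (ends - starts) > min_duration
  if (!any(keep)) return(epoch_set())
  epoch_set(starts[keep], ends[keep], rep(label, sum(keep)))
}

#' Normalized power-density spectrum of an LFP signal
#'
#' The signal is cut into non-overlapping 40 s segments (0.025 Hz FFT
#' resolution) with a rectangular window; per-segment FFT power is averaged,
#' raw bins below 1 Hz are discarded (they are noise-sensitive), bins above
#' 25 Hz are dropped, the remaining 0.025 Hz bins are averaged in groups of
#' 20 into 0.5 Hz bins, and the result is expressed as a percentage of the
#' total (values sum to 100).
#'
#' @param lfp an [lfp_signal] of at least 40 s.
#' @param f_min,f_max analysis range in Hz.
#' @param bin_width output bin width in Hz.
#' @return data frame of class `power_spectrum` with columns `freq` (bin
#'   centers, Hz) and `percent`; attribute `total_power` holds the
#'   pre-normalization one-sided power summed over the kept range (mean
#'   squared amplitude units).
#' @export
power_density <- function(lfp, f_min = 1, f_max = 25, bin_width = 0.5) {
  stopifnot(inherits(lfp, "lfp_signal"))
  seg_s <- 40
  seg_len <- round(seg_s * lfp$fs)
  n_seg <- length(lfp$samples) %/% seg_len
  if (n_seg < 1L)
    stop("power_density requires at least 40 s of signal (0.025 Hz ",
         "resolution needs 40 s segments)", call. = FALSE)
  df <- 1 / seg_s  # 0.025 Hz
  i_lo <- ceiling(f_min / df)           # first kept raw bin (>= f_min)
  i_hi <- floor((f_max - df) / df) + 1L # raw bins strictly below f_max, plus edge
  raw_f <- (i_lo:i_hi) * df
  raw_f <- raw_f[raw_f >= f_min & raw_f < f_max]
  idx <- round(raw_f / df)
  pow <- numeric(length(idx))
  for (s in seq_len(n_seg)) {
    seg <- lfp$samples[((s - 1L) * seg_len + 1L):(s * seg_len)]
    sp <- stats::fft(seg)
    # one-sided power, mean-square units
    p <- 2 * Mod(sp[idx + 1L])^2 / seg_len^2
    pow <- pow + p
  }
  pow <- pow / n_seg
  per_bin <- round(bin_width / df)
  n_bins <- length(pow) %/% per_bin
  pow <- pow[seq_len(n_bins * per_bin)]
  grp <- rep(seq_len(n_bins), each = per_bin)
  binned <- as.numeric(tapply(pow, grp, mean))
  centers <- f_min + (seq_len(n_bins) - 0.5) * bin_width
  total <- sum(pow)
  structure(data.frame(freq = centers, percent = 100 * binned / sum(binned)),
            class = c("power_spectrum", "data.frame"),
            total_power = total)
}
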