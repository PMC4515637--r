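# Event-aligned analyses: perievent Z-scored histograms, Early/Middle
# response subcategorization, and first-spike latency to pulse trains.

#' Perievent Z-scored firing-rate histogram
#'
#' Spike counts are binned relative to each event, converted to firing
#' rates, and standardized by the mean and SD of the rates in the baseline
#' (pre-event) bins: `z_b = (rate_b - mu_baseline) / sd_baseline`.
#'
#' @param train a [spike_train].
#' @param events event times (seconds), at least 5.
#' @param window analysis window around each event, `c(lo, hi)` seconds.
#' @param bin bin width in seconds.
#' @param baseline baseline window, must lie within `window`.
#' @return object of class `perievent_response`: list with `edges`,
#'   `centers`, `rate` (Hz), `z`, `baseline`, `n_events`.
#' @export
perievent_zscore <- function(train, events, window = c(-5, 5), bin = 0.1,
                             baseline = c(-5, 0)) {
  stopifnot(inherits(train, "spike_train"))
  events <- as.double(events)
  if (length(events) < 5L)
    stop("at least 5 events are required", call. = FALSE)
  if (baseline[1L] < window[1L] || baseline[2L] > window[2L])
    stop("baseline must lie within the analysis window", call. = FALSE)
  n_bins <- round((window[2L] - window[1L]) / bin)
  edges <- window[1L] + bin * (0:n_bins)
  counts <- numeric(n_bins)
  for (ev in events) {
    rel <- train$times - ev
    rel <- rel[rel >= window[1L] & rel < window[2L]]
    if (length(rel))
      counts <- counts + tabulate(
        findInterval(rel, edges, rightmost.closed = FALSE), nbins = n_bins)
  }
  rate <- counts / (length(events) * bin)
  centers <- edges[-length(edges)] + bin / 2
  base_bins <- centers > baseline[1L] & centers < baseline[2L]
  if (sum(base_bins) < 2L)
    stop("baseline window contains fewer than 2 bins", call. = FALSE)
  mu <- mean(rate[base_bins]); sdv <- stats::sd(rate[base_bins])
  if (sdv == 0)
    stop("baseline rate SD is zero; use a longer baseline or wider bins",
         call. = FALSE)
  structure(list(edges = edges, centers = centers, rate = rate,
                 z = (rate - mu) / sdv, baseline = baseline,
                 n_events = length(events)),
            class = "perievent_response")
}

run_exceeds <- function(flag, min_bins) {
  r <- rle(flag)
  any(r$values & r$lengths >= min_bins)
}

#' Classify an event-aligned response over Early and Middle windows
#'
#' Within each (disjoint, post-event) window the response is `Exc` when at
#' least `min_bins` consecutive bins have `z > z_crit`, `Inh` when at least
#' `min_bins` consecutive bins have `z < -z_crit`, else `None` (excitation
#' checked first). The subcategory label concatenates the two window calls,
#' e.g. `"Exc-Inh"`.
#'
#' @param resp a `perievent_response`.
#' @param early,middle window bounds `c(lo, hi)` in seconds after the event.
#' @param z_crit z threshold.
#' @param min_bins consecutive-bin persistence requirement.
#' @return list with `early`, `middle` (each `"Exc"`, `"Inh"` or `"None"`)
#'   and `label`.
#' @export
classify_response <- function(resp, early = c(0, 0.5), middle = c(0.5, 2),
                              z_crit = 2, min_bins = 2L) {
  stopifnot(inherits(resp, "perievent_response"))
  if (max(early[1L], middle[1L]) < min(early[2L], middle[2L]) &&
      !(early[2L] <= middle[1L] || middle[2L] <= early[1L]))
    stop("early and middle windows must be disjoint", call. = FALSE)
  call_window <- function(w) {
    sel <- resp$centers > w[1L] & resp$centers < w[2L]
    if (!any(sel)) return("None")
    z <- resp$z[sel]
    if (run_exceeds(z > z_crit, min_bins)) "Exc"
    else if (run_exceeds(z < -z_crit, min_bins)) "Inh"
    else "None"
  }
  e <- call_window(early); m <- call_window(middle)
  list(early = e, middle = m, label = paste(e, m, sep = "-"))
}

#' First-spike latency to stimulation pulses
#'
#' For each pulse, the latency of the first spike within the response
#' window after the pulse; pulses with no in-window spike are excluded.
#' Reported in milliseconds with the SEM over responsive pulses.
#'
#' @param train a [spike_train].
#' @param pulses pulse times in seconds, at least 1.
#' @param window response window after each pulse, seconds
#'   (default 0-10 ms).
#' @return list with `mean_ms`, `sem_ms`, `n_responsive`, `latencies_ms`;
#'   `mean_ms` is `NA` (with a warning) when no pulse is responsive.
#' @export
first_spike_latency <- function(train, pulses, window = c(0, 0.010)) {
  stopifnot(inherits(train, "spike_train"))
  pulses <- as.double(pulses)
  if (!length(pulses)) stop("at least one pulse is required", call. = FALSE)
  lat <- vapply(pulses, function(p) {
    inw <- train$times[train$times > p + window[1L] &
                         train$times <= p + window[2L]]
    if (length(inw)) inw[1L] - p else NA_real_
  }, numeric(1L))
  lat <- lat[!is.na(lat)] * 1000
  if (!length(lat)) {
    warning("no responsive pulses within the window; latency undefined")
    return(list(mean_ms = NA_real_, sem_ms = NA_real_, n_responsive = 0L,
                latencies_ms = numeric(0L)))
  }
  list(mean_ms = mean(lat),
       sem_ms = if (length(lat) > 1L) stats::sd(lat) / sqrt(length(lat)) else 0,
       n_responsive = length(lat),
       latencies_ms = lat)
}
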