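# Synthetic spike trains, populations, LFP and event-modulated trains with
# known ground truth. All generators are deterministic under a fixed seed.

#' Simulate a gamma-renewal spike train
#'
#' ISIs are drawn i.i.d. from Gamma(shape = `k`, scale = `theta`) and summed
#' cumulatively; the train is truncated at `duration`. `k = 1` gives a
#' Poisson process; larger `k` gives more regular firing (ISI coefficient of
#' variation `1/sqrt(k)`). Mean rate is `1 / (k * theta)` Hz.
#'
#' @param k gamma shape (> 0), the spike-regularity index.
#' @param theta gamma scale in seconds (> 0).
#' @param duration train length in seconds.
#' @param seed integer seed or `NULL` to use the current RNG stream.
#' @param unit_id unit name.
#' @return a [spike_train].
#' @export
simulate_gamma_train <- function(k, theta, duration, seed = NULL,
                                 unit_id = "unit1") {
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("`k` must be a positive shape parameter", call. = FALSE)
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0)
    stop("`theta` must be a positive scale (seconds)", call. = FALSE)
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  with_seed(seed, {
    mean_isi <- k * theta
    times <- numeric(0L)
    t_last <- 0
    repeat {
      n_draw <- max(1000L, ceiling((duration - t_last) / mean_isi * 1.2))
      isis <- stats::rgamma(n_draw, shape = k, scale = theta)
      times <- c(times, t_last + cumsum(isis))
      t_last <- times[length(times)]
      if (t_last > duration) break
    }
    spike_train(unit_id, times[times <= duration])
  })
}

#' Simulate a bursty spike train
#'
#' Burst events occur as a Poisson process at `burst_rate`; each event emits
#' a burst of spikes separated by `intra_burst_isi` (optionally jittered).
#' With a fixed burst size `m` and widely spaced events, the burst index
#' (fraction of ISIs under 10 ms) converges to `(m - 1) / m`. Burstiness and
#' the fitted gamma shape can thus be controlled independently of the event
#' rate, breaking the renewal coupling `cv = 1/sqrt(k)`.
#'
#' @param burst_rate burst-event rate in Hz.
#' @param spikes_per_burst either a single integer, or a list with elements
#'   `size` (integer vector) and `prob` (sampling weights).
#' @param intra_burst_isi within-burst ISI in seconds; must be below the
#'   0.010 s burst definition and below the mean event spacing.
#' @param duration train length in seconds.
#' @param jitter_sd Gaussian jitter SD (seconds) on within-burst ISIs.
#' @param seed integer seed or `NULL`.
#' @param unit_id unit name.
#' @return a [spike_train].
#' @export
simulate_burst_train <- function(burst_rate, spikes_per_burst = 3L,
                                 intra_burst_isi = 0.005, duration = 600,
                                 jitter_sd = 0, seed = NULL,
                                 unit_id = "unit1") {
  if (burst_rate <= 0) stop("`burst_rate` must be positive", call. = FALSE)
  if (intra_burst_isi <= 0 || intra_burst_isi >= 0.010)
    stop("`intra_burst_isi` must lie in (0, 0.010) s so within-burst ISIs ",
         "count as bursts", call. = FALSE)
  if (intra_burst_isi >= 1 / burst_rate)
    stop("`intra_burst_isi` must be much smaller than the mean burst spacing ",
         sprintf("(1/burst_rate = %.3f s)", 1 / burst_rate), call. = FALSE)
  if (is.list(spikes_per_burst)) {
    sizes <- as.integer(spikes_per_burst$size)
    probs <- as.double(spikes_per_burst$prob)
    if (length(sizes) != length(probs) || any(sizes < 1L) || any(probs < 0))
      stop("invalid spikes_per_burst distribution spec", call. = FALSE)
  } else {
    sizes <- as.integer(spikes_per_burst)
    probs <- 1
    if (length(sizes) != 1L || sizes < 1L)
      stop("`spikes_per_burst` must be a positive integer or a ",
           "list(size=, prob=)", call. = FALSE)
  }
  with_seed(seed, {
    n_ev <- stats::rpois(1L, burst_rate * duration * 1.5) + 50L
    ev <- cumsum(stats::rexp(n_ev, rate = burst_rate))
    ev <- ev[ev <= duration]
    if (!length(ev)) return(spike_train(unit_id, numeric(0L)))
    m <- if (length(sizes) == 1L) rep.int(sizes, length(ev)) else
      sample(sizes, length(ev), replace = TRUE, prob = probs)
    times <- unlist(lapply(seq_along(ev), function(i) {
      offs <- (seq_len(m[i]) - 1L) * intra_burst_isi
      if (jitter_sd > 0 && m[i] > 1L) {
        d <- abs(diff(offs) + stats::rnorm(m[i] - 1L, 0, jitter_sd))
        offs <- c(0, cumsum(d))
      }
      ev[i] + offs
    }))
    times <- unique(sort(times))
    spike_train(unit_id, times[times <= duration])
  })
}

#' Simulate a multi-subtype unit population
#'
#' Each subtype draws per-unit parameters uniformly within its ranges and
#' generates an independent train. Per-unit seeds are derived from the root
#' seed and a global unit index, so adding subtypes or units never perturbs
#' previously generated trains.
#'
#' @param subtypes list of subtype specs; each a list with `n_units`,
#'   `k_range` (length-2, gamma shapes), `rate_range` (length-2, Hz), and
#'   `process` (`"gamma"` or `"burst"`). Burst subtypes may add
#'   `spikes_per_burst` and `intra_burst_isi`; for them `rate_range` is the
#'   burst-event rate and `k_range` is ignored.
#' @param duration train length in seconds.
#' @param seed root integer seed.
#' @param session_id session label.
#' @return list with `set` (a [spike_train_set]), `labels` (data frame
#'   `unit_id`, `subtype`) and `params` (per-unit generating parameters).
#' @export
simulate_population <- function(subtypes, duration = 1800, seed = 1,
                                session_id = "synthetic") {
  if (!length(subtypes)) stop("`subtypes` must be non-empty", call. = FALSE)
  trains <- list(); labels <- character(0L); params <- list()
  idx <- 0L
  for (s in seq_along(subtypes)) {
    st <- subtypes[[s]]
    if (is.null(st$n_units) || st$n_units < 1L)
      stop("each subtype needs n_units >= 1", call. = FALSE)
    proc <- st$process %||% "gamma"
    for (u in seq_len(st$n_units)) {
      idx <- idx + 1L
      sub_seed <- derive_seed(seed, idx)
      uid <- sprintf("u%03d", idx)
      pr <- with_seed(sub_seed, list(
        k = stats::runif(1L, st$k_range[1L], st$k_range[2L] %||% st$k_range[1L]),
        rate = stats::runif(1L, st$rate_range[1L],
                            st$rate_range[2L] %||% st$rate_range[1L])
      ))
      if (proc == "gamma") {
        tr <- simulate_gamma_train(pr$k, theta = 1 / (pr$k * pr$rate),
                                   duration = duration,
                                   seed = derive_seed(sub_seed, 1L),
                                   unit_id = uid)
      } else if (proc == "burst") {
        tr <- simulate_burst_train(
          burst_rate = pr$rate,
          spikes_per_burst = st$spikes_per_burst %||% 3L,
          intra_burst_isi = st$intra_burst_isi %||% 0.005,
          duration = duration, seed = derive_seed(sub_seed, 1L),
          unit_id = uid)
      } else stop("unknown process: ", proc, call. = FALSE)
      trains[[idx]] <- tr
      labels[idx] <- st$name %||% paste0("subtype", s)
      params[[idx]] <- c(unit = uid, subtype = labels[idx],
                         k = pr$k, rate = pr$rate)
    }
  }
  list(set = spike_train_set(trains, session_id = session_id),
       labels = data.frame(unit_id = vapply(trains, `[[`, character(1L), "unit_id"),
                           subtype = labels, stringsAsFactors = FALSE),
       params = do.call(rbind, lapply(params, function(p)
         data.frame(as.list(p), stringsAsFactors = FALSE))))
}

#' Simulate a band-limited LFP trace
#'
#' The signal is white Gaussian noise plus scheduled sinusoidal components,
#' each active on its own `[start, end)` interval — a controllable fixture
#' for state detection from band power.
#'
#' @param components data frame with columns `freq` (Hz), `amplitude`,
#'   `start`, `end` (seconds). May have zero rows for pure noise.
#' @param fs sampling rate in Hz; must exceed twice the highest component
#'   frequency.
#' @param duration seconds.
#' @param noise_sd white-noise standard deviation.
#' @param seed integer seed or `NULL`.
#' @return an [lfp_signal].
#' @export
simulate_lfp <- function(components, fs, duration, noise_sd = 1, seed = NULL) {
  components <- as.data.frame(components)
  if (nrow(components) && fs <= 2 * max(components$freq))
    stop(sprintf("fs = %g Hz violates Nyquist for a %g Hz component",
                 fs, max(components$freq)), call. = FALSE)
  with_seed(seed, {
    n <- round(duration * fs)
    t <- (seq_len(n) - 1L) / fs
    x <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
    for (j in seq_len(nrow(components))) {
      on <- t >= components$start[j] & t < components$end[j]
      x[on] <- x[on] +
        components$amplitude[j] * sin(2 * pi * components$freq[j] * t[on])
    }
    lfp_signal(x, fs = fs, t0 = 0)
  })
}

#' Simulate an event-modulated (inhomogeneous Poisson) spike train
#'
#' The baseline rate is multiplied, within given peri-event windows, by the
#' window's rate multiplier; spikes are generated by thinning a homogeneous
#' Poisson process at the maximal rate. Windows are offsets relative to each
#' event and must not overlap one another.
#'
#' @param baseline_rate baseline firing rate in Hz.
#' @param events event times in seconds.
#' @param profile data frame with columns `start`, `end` (offsets, seconds)
#'   and `multiplier` (>= 0); `NULL` for an unmodulated train.
#' @param duration train length in seconds.
#' @param seed integer seed or `NULL`.
#' @param unit_id unit name.
#' @return a [spike_train].
#' @export
simulate_perievent_train <- function(baseline_rate, events, profile = NULL,
                                     duration, seed = NULL,
                                     unit_id = "unit1") {
  if (baseline_rate <= 0) stop("`baseline_rate` must be positive", call. = FALSE)
  if (!is.null(profile)) {
    profile <- as.data.frame(profile)
    if (any(profile$multiplier < 0))
      stop("rate multipliers must be >= 0", call. = FALSE)
    if (nrow(profile) > 1L) {
      o <- order(profile$start)
      if (any(profile$start[o][-1L] < profile$end[o][-nrow(profile)]))
        stop("profile windows overlap", call. = FALSE)
    }
  }
  rate_at <- function(t) {
    r <- rep.int(baseline_rate, length(t))
    if (is.null(profile) || !length(events)) return(r)
    for (j in seq_len(nrow(profile))) {
      for (ev in events) {
        in_w <- t >= ev + profile$start[j] & t < ev + profile$end[j]
        r[in_w] <- baseline_rate * profile$multiplier[j]
      }
    }
    r
  }
  r_max <- baseline_rate * max(1, if (is.null(profile)) 1 else
    max(profile$multiplier))
  with_seed(seed, {
    n_cand <- stats::rpois(1L, r_max * duration)
    cand <- sort(stats::runif(n_cand, 0, duration))
    keep <- stats::runif(n_cand) < rate_at(cand) / r_max
    spike_train(unit_id, cand[keep])
  })
}
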