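# Containers and readers for spike trains, epochs, LFP and feature tables.
# Time is always seconds.

#' Construct a spike train
#'
#' A spike train is the ordered list of action-potential timestamps of one
#' unit. Times are sorted, must be finite and non-negative, and exact
#' duplicates are collapsed with a warning.
#'
#' @param unit_id character scalar naming the unit.
#' @param times numeric vector of spike times in seconds.
#' @return an object of class `spike_train`: a list with `unit_id`, `times`.
#' @export
spike_train <- function(unit_id, times) {
  if (!is.character(unit_id) || length(unit_id) != 1L)
    stop("`unit_id` must be a single string", call. = FALSE)
  times <- as.double(times)
  if (anyNA(times) || any(!is.finite(times)))
    stop("spike times must all be finite", call. = FALSE)
  if (any(times < 0))
    stop("spike times must be non-negative (seconds)", call. = FALSE)
  times <- sort(times)
  if (anyDuplicated(times)) {
    n_dup <- sum(duplicated(times))
    warning(sprintf("unit '%s': collapsed %d duplicate timestamp(s)",
                    unit_id, n_dup), call. = FALSE)
    times <- unique(times)
  }
  structure(list(unit_id = unit_id, times = times), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train '%s': %d spikes", x$unit_id, length(x$times)))
  if (length(x$times))
    cat(sprintf(", %.3f-%.3f s", x$times[1L], x$times[length(x$times)]))
  cat(">\n")
  invisible(x)
}

#' Construct a set of spike trains
#'
#' @param trains list of [spike_train] objects with unique unit ids.
#' @param session_id character scalar.
#' @return object of class `spike_train_set` with elements `trains`
#'   (named by unit id) and `session_id`.
#' @export
spike_train_set <- function(trains, session_id = "session") {
  if (!length(trains)) stop("`trains` must be non-empty", call. = FALSE)
  ok <- vapply(trains, inherits, logical(1L), what = "spike_train")
  if (!all(ok)) stop("all elements must be spike_train objects", call. = FALSE)
  ids <- vapply(trains, `[[`, character(1L), "unit_id")
  if (anyDuplicated(ids))
    stop("duplicate unit_id in spike train set: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(trains) <- ids
  structure(list(trains = trains, session_id = session_id),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("<spike_train_set '%s': %d units>\n",
              x$session_id, length(x$trains)))
  invisible(x)
}

#' Read spike times from disk
#'
#' Two plain-text dialects are supported. The canonical `"long"` dialect is a
#' CSV with header `unit_id,time_s`, one spike per row. The `"per-unit"`
#' dialect is one file per unit holding one timestamp per line; the unit id
#' is the file name without extension, and `path` may be a single file or a
#' directory of such files.
#'
#' @param path file (or, for `"per-unit"`, file or directory) to read.
#' @param dialect `"long"` or `"per-unit"`.
#' @param session_id session label for the returned set.
#' @return a [spike_train_set].
#' @export
read_spike_times <- function(path, dialect = c("long", "per-unit"),
                             session_id = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "long") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("unit_id", "time_s")
    if (!all(need %in% names(tab)))
      stop("long-table spike file must have columns unit_id,time_s", call. = FALSE)
    t_num <- suppressWarnings(as.double(tab$time_s))
    bad <- which(is.na(t_num) | !is.finite(t_num))
    if (length(bad))
      stop(sprintf("malformed time_s at data line(s) %s of %s",
                   paste(utils::head(bad, 5L), collapse = ", "), path),
           call. = FALSE)
    if (any(t_num < 0)) {
      bad <- which(t_num < 0)
      stop(sprintf("negative spike time at data line(s) %s of %s",
                   paste(utils::head(bad, 5L), collapse = ", "), path),
           call. = FALSE)
    }
    split_times <- split(t_num, as.character(tab$unit_id))
    trains <- lapply(names(split_times), function(id)
      spike_train(id, split_times[[id]]))
  } else {
    files <- if (dir.exists(path))
      list.files(path, full.names = TRUE) else path
    if (!length(files)) stop("no per-unit files found in ", path, call. = FALSE)
    trains <- lapply(files, function(f) {
      lines <- readLines(f, warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      vals <- suppressWarnings(as.double(lines))
      if (anyNA(vals))
        stop(sprintf("malformed line %d of %s", which(is.na(vals))[1L], f),
             call. = FALSE)
      spike_train(sub("\\.[^.]*$", "", basename(f)), vals)
    })
  }
  spike_train_set(trains, session_id = session_id)
}

#' Construct a labeled epoch set
#'
#' Epochs are half-open intervals `[start, end)` in seconds with a state
#' label (for example `"awake"`, `"SWS"`, `"anesthesia"`). Epochs sharing a
#' label must not overlap.
#'
#' @param start,end numeric vectors of epoch bounds in seconds.
#' @param label character vector of state labels.
#' @return a data frame of class `epoch_set` with columns `start`, `end`,
#'   `label`.
#' @export
epoch_set <- function(start = numeric(), end = numeric(), label = character()) {
  start <- as.double(start); end <- as.double(end); label <- as.character(label)
  if (length(start) != length(end) || length(start) != length(label))
    stop("start, end and label must have equal length", call. = FALSE)
  if (any(!is.finite(start)) || any(!is.finite(end)))
    stop("epoch bounds must be finite", call. = FALSE)
  if (any(start >= end))
    stop("every epoch must satisfy start < end", call. = FALSE)
  for (lab in unique(label)) {
    i <- which(label == lab)
    if (length(i) > 1L) {
      o <- i[order(start[i])]
      if (any(start[o][-1L] < end[o][-length(o)]))
        stop("overlapping epochs share label '", lab, "'", call. = FALSE)
    }
  }
  structure(data.frame(start = start, end = end, label = label,
                       stringsAsFactors = FALSE),
            class = c("epoch_set", "data.frame"))
}

#' Read an epoch table
#'
#' CSV with header `start_s,end_s,label`.
#'
#' @param path file to read.
#' @return an [epoch_set].
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_s", "end_s", "label")
  if (!all(need %in% names(tab)))
    stop("epoch file must have columns start_s,end_s,label", call. = FALSE)
  epoch_set(tab$start_s, tab$end_s, tab$label)
}

#' Write / read a per-unit feature table
#'
#' Feature tables are tab-separated text with a header row, one unit per
#' row. `read_features(write_features(x, f))` reproduces `x` at the level of
#' the formatted text.
#'
#' @param features data frame of per-unit features.
#' @param path file to write or read.
#' @return `write_features` returns `path` invisibly; `read_features` returns
#'   the data frame.
#' @export
write_features <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Construct an LFP signal
#'
#' @param samples numeric vector (arbitrary units).
#' @param fs sampling rate in Hz (> 0).
#' @param t0 time of the first sample in seconds.
#' @return object of class `lfp_signal`.
#' @export
lfp_signal <- function(samples, fs, t0 = 0) {
  samples <- as.double(samples)
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("LFP samples must be finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive sampling rate in Hz", call. = FALSE)
  structure(list(samples = samples, fs = as.double(fs), t0 = as.double(t0)),
            class = "lfp_signal")
}

#' Read an LFP trace
#'
#' Samples are read from a one-column CSV (header `sample`) or a plain text
#' file with one value per line; sampling metadata comes from a JSON sidecar
#' `{"fs_hz": ..., "t0_s": ...}`.
#'
#' @param path sample file.
#' @param meta_path JSON sidecar; defaults to `path` with a `.json` suffix.
#' @return an [lfp_signal].
#' @export
read_lfp <- function(path, meta_path = paste0(path, ".json")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!file.exists(meta_path))
    stop("metadata sidecar not found: ", meta_path, call. = FALSE)
  meta <- jsonlite::fromJSON(meta_path)
  if (is.null(meta$fs_hz)) stop("sidecar must provide fs_hz", call. = FALSE)
  if (grepl("\\.csv$", path)) {
    samples <- utils::read.csv(path)[[1L]]
  } else {
    samples <- as.double(readLines(path, warn = FALSE))
  }
  lfp_signal(samples, fs = meta$fs_hz, t0 = meta$t0_s %||% 0)
}

#' Restrict a spike train to the epochs of one state
#'
#' Keeps the spikes falling inside any epoch carrying `label` (half-open
#' intervals) and records which inter-spike intervals are valid: an ISI is
#' excluded when its two spikes fall in different epochs, so downstream ISI
#' statistics never include artificial gap intervals that straddle an epoch
#' boundary.
#'
#' @param train a [spike_train].
#' @param epochs an [epoch_set].
#' @param label state label to keep.
#' @return a [spike_train] with attribute `isi_valid`, a logical vector of
#'   length `n_spikes - 1` marking ISIs that lie within a single epoch.
#' @export
restrict_to_epochs <- function(train, epochs, label) {
  stopifnot(inherits(train, "spike_train"), inherits(epochs, "epoch_set"))
  sel <- epochs$label == label
  if (!any(sel))
    stop("no epochs labeled '", label, "'; available: ",
         paste(unique(epochs$label), collapse = ", "), call. = FALSE)
  eps <- epochs[sel, , drop = FALSE]
  times <- train$times
  which_ep <- rep(NA_integer_, length(times))
  for (j in seq_len(nrow(eps))) {
    inside <- times >= eps$start[j] & times < eps$end[j]
    which_ep[inside] <- j
  }
  keep <- !is.na(which_ep)
  out <- spike_train(train$unit_id, times[keep])
  ep_kept <- which_ep[keep]
  n <- length(out$times)
  attr(out, "isi_valid") <-
    if (n >= 2L) ep_kept[-1L] == ep_kept[-n] else logical(0L)
  attr(out, "state_duration") <- sum(eps$end - eps$start)
  out
}
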