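# End-to-end orchestration of the four-stage classification pipeline.

#' Run the full inter-spike-interval classification pipeline
#'
#' Executes the four stages in order: (1) per-unit feature extraction
#' (gamma MLE k and theta, cv, burst index, rate) restricted to one brain
#' state; (2) normality pre-screen of the clustered features; (3) restarted
#' cosine k-means over `(k, cv)` with jump-method selection of the cluster
#' count; (4) Monte-Carlo cluster-index validation against a single
#' multivariate Gaussian null. A single root seed fans out to fixed
#' substreams for clustering and the null, so each stage is independently
#' reproducible and the whole run is deterministic.
#'
#' @param spikes a [spike_train_set] or path to a long-table spike CSV.
#' @param epochs optional [epoch_set] or path to an epoch CSV.
#' @param state state label within `epochs` to analyze.
#' @param k_max largest cluster count examined.
#' @param n_restarts k-means restarts per K.
#' @param Y jump transform power (default p/2).
#' @param n_sim Monte-Carlo draws for validation (0 skips validation).
#' @param alpha pre-screen rejection level.
#' @param force_cluster proceed to clustering even when no feature rejects
#'   normality.
#' @param min_isi gamma-fit ISI-count threshold.
#' @param seed root integer seed.
#' @param out_dir if given, writes `features.tsv`, `clusters.tsv`,
#'   `validation.json` and `log.txt` there.
#' @return list with `features`, `excluded`, `screen`, `clustering`,
#'   `validation`, `config`, `log`.
#' @export
run_isica <- function(spikes, epochs = NULL, state = NULL, k_max = 8L,
                      n_restarts = 10000L, Y = NULL, n_sim = 10000L,
                      alpha = 0.05, force_cluster = FALSE, min_isi = 250L,
                      seed = 1L, out_dir = NULL) {
  if (is.character(spikes)) spikes <- read_spike_times(spikes)
  if (is.character(epochs)) epochs <- read_epochs(epochs)
  n_units <- length(spikes$trains)
  if (k_max > n_units)
    stop("k_max = ", k_max, " exceeds the number of units (", n_units,
         "); lower k_max", call. = FALSE)
  log_lines <- c(sprintf("units in: %d", n_units))

  fm <- extract_features(spikes, epochs = epochs, label = state,
                         min_isi = min_isi)
  excl <- attr(fm, "excluded")
  log_lines <- c(log_lines,
                 sprintf("features: %d units fitted, %d excluded", nrow(fm),
                         nrow(excl)),
                 if (nrow(excl)) sprintf("  excluded %s: %s", excl$unit_id,
                                         excl$reason))

  scr <- screen_features(fm, alpha = alpha)
  log_lines <- c(log_lines, sprintf(
    "prescreen: %s (min p = %.3g)",
    if (scr$proceed) "normality rejected; clustering justified" else
      "normality not rejected", min(scr$reports$p_value)))
  if (!scr$proceed && !force_cluster)
    stop("no clustered feature rejects normality at alpha = ", alpha,
         "; the population looks homogeneous. Re-run with ",
         "force_cluster = TRUE to cluster anyway.", call. = FALSE)

  k_max_eff <- min(k_max, nrow(fm))
  cl <- jump_select_k(fm, k_max = k_max_eff, Y = Y,
                      n_restarts = n_restarts, seed = derive_seed(seed, 1L))
  log_lines <- c(log_lines, sprintf("clustering: selected K = %d", cl$selected_K))

  val <- NULL
  if (n_sim > 0 && cl$selected_K > 1L) {
    val <- gaussian_null_pvalue(fm, K = cl$selected_K, n_sim = n_sim,
                                seed = derive_seed(seed, 2L))
    log_lines <- c(log_lines,
                   sprintf("validation: observed ci = %.4g, p = %.4g",
                           val$observed_ci, val$p_value))
  }

  config <- list(state = state, k_max = k_max, n_restarts = n_restarts,
                 Y = cl$Y, n_sim = n_sim, alpha = alpha,
                 force_cluster = force_cluster, min_isi = min_isi,
                 seed = seed)
  result <- list(features = fm, excluded = excl, screen = scr,
                 clustering = cl, validation = val, config = config,
                 log = log_lines)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_features(fm, file.path(out_dir, "features.tsv"))
    clusters <- data.frame(unit_id = fm$unit_id, cluster = cl$labels)
    write_features(clusters, file.path(out_dir, "clusters.tsv"))
    jsonlite::write_json(
      list(config = config,
           selected_K = cl$selected_K,
           distortion_by_K = cl$distortion_by_K,
           jumps = cl$jumps,
           validation = if (is.null(val)) NULL else
             val[c("observed_ci", "n_sim", "p_value", "direction")]),
      file.path(out_dir, "validation.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "log.txt"))
  }
  result
}
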