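# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so library code never clobbers the caller's stream.
#' A `NULL` seed evaluates `code` against the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Stable per-unit substream: adding units never perturbs earlier ones.
# Kept below 2^31 and exact in double arithmetic.
derive_seed <- function(seed, index) {
  as.integer((abs(as.double(seed)) * 69069 + as.double(index) * 1234567) %%
               2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# coerce a feature table / matrix to the numeric matrix that is clustered
as_feature_matrix <- function(X, columns = c("k", "cv")) {
  if (is.data.frame(X)) {
    missing_cols <- setdiff(columns, names(X))
    if (length(missing_cols))
      stop("feature table lacks column(s): ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    M <- as.matrix(X[columns])
    rownames(M) <- if ("unit_id" %in% names(X)) as.character(X$unit_id) else NULL
  } else {
    M <- as.matrix(X)
  }
  storage.mode(M) <- "double"
  if (!nrow(M)) stop("empty feature matrix", call. = FALSE)
  if (anyNA(M) || any(!is.finite(M)))
    stop("feature matrix contains missing or non-finite values", call. = FALSE)
  M
}
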