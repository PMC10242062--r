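#' Derive a reproducible sub-stream seed
#'
#' Expands a single user-facing seed into independent named sub-streams
#' (feature selection, k-means restarts, VAE initialization, simulation
#' replicates, ...) so that component-level reproducibility survives
#' composition: changing the number of k-means restarts, say, does not
#' perturb the simulated data.
#'
#' @param seed integer base seed (kept below 2^31).
#' @param tag character stream name.
#' @param i optional replicate counter within the stream.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag, i = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  # all intermediate values stay well below 2^53, so double arithmetic is exact
  v <- (abs(seed) %% 2147483647) * 48271 + h * 7919 + as.double(i) * 104729
  as.integer(v %% 2147483646) + 1L
}

# Evaluate `expr` under a local RNG state: seeds with `seed` and restores the
# caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# shared input check: numeric matrix, finite entries
check_finite_matrix <- function(X, what = "matrix") {
  if (!is.matrix(X) || !is.numeric(X))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(X)))
    stop(what, " contains non-finite entries (NA/NaN/Inf are not supported)",
         call. = FALSE)
  invisible(X)
}
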