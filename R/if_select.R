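#' Kolmogorov-Smirnov feature score
#'
#' Computes `sqrt(n) * sup_t |F_n(t) - F(t)|` where `F_n` is the empirical
#' CDF of the studentized values `(z_i - mean(z)) / sd(z)` and `F` is the
#' standard normal reference CDF. The supremum is computed exactly as the
#' maximum over order statistics `u_(1) <= ... <= u_(n)` of
#' `max(i/n - F(u_(i)), F(u_(i)) - (i-1)/n)`.
#'
#' Strictly, the null reference for studentized normal samples is not the
#' standard normal CDF; the first-order difference is absorbed downstream by
#' Efron's empirical-null standardization (see [efron_standardize()]). The
#' exact studentized null can be simulated with [ks_null_distribution()] for
#' validation.
#'
#' @param z numeric vector, length >= 3, non-constant.
#' @return nonnegative scalar score.
#' @export
ks_statistic <- function(z) {
  stopifnot(is.numeric(z))
  n <- length(z)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  s <- stats::sd(z)
  if (!is.finite(s) || s <= 0)
    stop("degenerate input: constant vector has no KS score", call. = FALSE)
  u <- sort((z - mean(z)) / s)
  Fu <- stats::pnorm(u)
  i <- seq_len(n)
  sqrt(n) * max(pmax(i / n - Fu, Fu - (i - 1) / n))
}

#' Simulate the exact null distribution of the KS score
#'
#' Monte-Carlo reference for [ks_statistic()]: draws `reps` standard normal
#' samples of size `n` and returns their KS scores, i.e. the null law of the
#' statistic under studentization.
#'
#' @param n sample size.
#' @param reps number of Monte-Carlo replicates (default 10000).
#' @param seed integer seed.
#' @return numeric vector of `reps` null scores.
#' @export
ks_null_distribution <- function(n, reps = 10000L, seed = 1L) {
  with_seed(seed, {
    vapply(seq_len(reps), function(i) ks_statistic(stats::rnorm(n)), 0)
  })
}

#' Efron's empirical-null standardization
#'
#' Standardizes a vector of feature scores by its own empirical mean and
#' standard deviation: `psi*_j = (phi_j - mu*) / sigma*`. Because the null
#' law of the scores is estimated from the data themselves, the correction
#' is invariant to increasing affine transformations of the scores.
#'
#' @param phi numeric score vector, length >= 2, non-constant.
#' @return list with `psi_star`, `mu_star`, `sigma_star` (sample sd).
#' @export
efron_standardize <- function(phi) {
  stopifnot(is.numeric(phi), length(phi) >= 2L)
  mu <- mean(phi)
  sig <- stats::sd(phi)
  if (!is.finite(sig) || sig <= 0)
    stop("degenerate scores: zero standard deviation", call. = FALSE)
  list(psi_star = (phi - mu) / sig, mu_star = mu, sigma_star = sig)
}

#' Upper-tail p-values for standardized KS scores
#'
#' `pi_j = P(N(0,1) > psi*_j)`, clamped to the open interval (eps, 1-eps)
#' so that the higher-criticism functional stays finite.
#'
#' @param psi_star numeric vector of standardized scores.
#' @return p-values in (0, 1), strictly decreasing in `psi_star`.
#' @export
ks_pvalues <- function(psi_star) {
  if (any(!is.finite(psi_star))) stop("non-finite scores", call. = FALSE)
  eps <- 1e-15
  pmin(pmax(stats::pnorm(psi_star, lower.tail = FALSE), eps), 1 - eps)
}

#' Higher-criticism threshold
#'
#' Sorts the p-values ascending and evaluates the feature-wise
#' higher-criticism score
#' `HC_{p,j} = sqrt(p) (j/p - pi_(j)) / sqrt(max(sqrt(n) (j/p - pi_(j)), 0) + j/p)`.
#' The threshold is `t_HC = pi_(j_hat)` where `j_hat` maximizes `HC_{p,j}`
#' over the admissible set `{ j : pi_(j) > log(p)/p, j < p/2 }`; ties break
#' to the smallest j. If no index is admissible (all small p-values), the
#' maximizer is taken over `{ j : j < p/2 }` and `fallback_used` is set.
#'
#' @param pvalues numeric vector of p-values in (0, 1), length >= 4.
#' @param n number of subjects behind the scores.
#' @return object of class `"hc_threshold"`: list with `hc_curve` (scores in
#'   sorted-p order), `j_hat`, `t_hc`, `order` (permutation sorting the
#'   input), `fallback_used`.
#' @export
hc_threshold <- function(pvalues, n) {
  p <- length(pvalues)
  if (p < 4L) stop("need at least 4 p-values", call. = FALSE)
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues >= 1))
    stop("p-values must lie strictly in (0, 1)", call. = FALSE)
  ord <- order(pvalues)                    # stable for ties
  ps <- pvalues[ord]
  j <- seq_len(p)
  gap <- j / p - ps
  hc <- sqrt(p) * gap / sqrt(pmax(sqrt(n) * gap, 0) + j / p)
  below_half <- j < p / 2
  admissible <- below_half & (ps > log(p) / p)
  fallback <- !any(admissible)
  cand <- if (fallback) which(below_half) else which(admissible)
  if (length(cand) == 0L) cand <- 1L       # p = 4 edge: j < 2 means j = 1
  j_hat <- cand[which.max(hc[cand])]
  structure(list(hc_curve = unname(hc), j_hat = j_hat,
                 t_hc = unname(ps[j_hat]),
                 order = ord, fallback_used = fallback),
            class = "hc_threshold")
}

#' @export
print.hc_threshold <- function(x, ...) {
  cat(sprintf("HC threshold: j_hat=%d, t_HC=%.4g%s\n", x$j_hat, x$t_hc,
              if (x$fallback_used) " (fallback: empty admissible set)" else ""))
  invisible(x)
}

#' The IF step: KS screening with a higher-criticism threshold
#'
#' Runs the complete influential-feature selection on a column-standardized
#' matrix: per-feature KS scores, Efron's empirical-null standardization,
#' normal upper-tail p-values, and the higher-criticism threshold. Features
#' with `pi_j <= t_HC` are retained. If fewer than `min_retained` survive,
#' the retained set is topped up with the smallest-p-value features (so a
#' downstream rank-(K-1) SVD stays well-posed) and `augmented` is flagged.
#'
#' @param W normalized matrix from [normalize_columns()] (any numeric matrix
#'   with standardized columns is accepted).
#' @param min_retained minimum size of the retained set (default 1).
#' @return object of class `"if_selection"`: list with `phi`, `psi_star`,
#'   `mu_star`, `sigma_star`, `pvalues`, `hc` (an `"hc_threshold"`),
#'   `t_hc`, `retained` (sorted column indices into `W`), `augmented`,
#'   `feature_ids`.
#' @export
select_features <- function(W, min_retained = 1L) {
  W <- as.matrix(W)
  check_finite_matrix(as_plain_matrix(W), "normalized matrix")
  stopifnot(min_retained >= 1L)
  p <- ncol(W)
  phi <- apply(as_plain_matrix(W), 2L, ks_statistic)
  if (stats::sd(phi) <= 0) {
    # all scores identical (e.g. noiseless planted data where every
    # informative column is the same two-point profile): no feature can be
    # distinguished from any other, so every feature is retained
    ef <- list(psi_star = rep(0, p), mu_star = mean(phi), sigma_star = 0)
  } else {
    ef <- efron_standardize(phi)
  }
  pv <- ks_pvalues(ef$psi_star)
  hc <- hc_threshold(pv, n = nrow(W))
  retained <- which(pv <= hc$t_hc)
  augmented <- FALSE
  if (length(retained) < min_retained) {
    augmented <- TRUE
    retained <- union(retained, order(pv)[seq_len(min_retained)])
  }
  structure(list(phi = phi, psi_star = ef$psi_star, mu_star = ef$mu_star,
                 sigma_star = ef$sigma_star, pvalues = pv, hc = hc,
                 t_hc = hc$t_hc, retained = sort(retained),
                 augmented = augmented,
                 feature_ids = colnames(W)),
            class = "if_selection")
}

#' @export
print.if_selection <- function(x, ...) {
  cat(sprintf("IF selection: %d of %d features retained (t_HC = %.4g)%s\n",
              length(x$retained), length(x$phi), x$t_hc,
              if (x$augmented) ", augmented to minimum size" else ""))
  invisible(x)
}

#' @export
as.data.frame.if_selection <- function(x, ...) {
  data.frame(
    feature_id = if (is.null(x$feature_ids)) seq_along(x$phi) else x$feature_ids,
    phi = x$phi, psi_star = x$psi_star, pvalue = x$pvalues,
    retained = as.integer(seq_along(x$phi) %in% x$retained),
    row.names = NULL)
}

#' Serialize an IF selection to TSV + JSON sidecar
#'
#' Writes the per-feature table (feature_id, phi, psi_star, pvalue,
#' retained) to `path` and the threshold metadata (t_HC, j_hat, fallback,
#' Efron parameters) to `<path>.json`.
#'
#' @param x an `"if_selection"`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(x, path) {
  stopifnot(inherits(x, "if_selection"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(t_hc = x$t_hc, j_hat = x$hc$j_hat,
               fallback_used = x$hc$fallback_used, augmented = x$augmented,
               mu_star = x$mu_star, sigma_star = x$sigma_star,
               n_retained = length(x$retained), p = length(x$phi))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
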