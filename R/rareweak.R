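#' Rare/weak model calibration
#'
#' Parameterizes the two-class rare/weak planted-signal model by the
#' dimension p and three exponents: sample size `n = round(p^theta)`, signal
#' sparsity `eps = p^-beta` (fraction of influential features), and signal
#' strength `tau = p^-alpha` (magnitude of each nonzero mean contrast).
#' `s_p = p * eps` is the expected number of influential features. Exact
#' powers are used for eps and tau; only n is rounded.
#'
#' @param p dimension (number of features).
#' @param theta,beta,alpha exponents in (0, 1) (alpha may exceed 1 to probe
#'   vanishing signals).
#' @return list of class `"rw_params"` with `p, theta, beta, alpha, n, eps,
#'   tau, s_p`.
#' @export
rw_params <- function(p, theta, beta, alpha) {
  stopifnot(p >= 2, theta > 0, theta < 1, beta > 0, beta < 1, alpha > 0)
  n <- round(p^theta)
  if (n < 2) stop("infeasible calibration: n = round(p^theta) < 2", call. = FALSE)
  structure(list(p = as.integer(p), theta = theta, beta = beta, alpha = alpha,
                 n = as.integer(n), eps = p^(-beta), tau = p^(-alpha),
                 s_p = p^(1 - beta)),
            class = "rw_params")
}

#' @export
print.rw_params <- function(x, ...) {
  cat(sprintf("rare/weak: p=%d theta=%.3g beta=%.3g alpha=%.3g -> n=%d eps=%.3g tau=%.3g s_p=%.3g\n",
              x$p, x$theta, x$beta, x$alpha, x$n, x$eps, x$tau, x$s_p))
  invisible(x)
}

#' Simulate a rare/weak instance
#'
#' Draws class labels `Y_i` iid uniform on \{-1, +1\}, a contrast vector
#' `mu` whose entries are 0 with probability `1 - eps` and `+-tau` with
#' probability `eps/2` each, and data `X = Y mu' + Z` with standard normal
#' noise. `tau` can be overridden (e.g. to probe a specific signal strength
#' at fixed sparsity).
#'
#' @param params an [rw_params()].
#' @param seed integer seed.
#' @param tau optional override of the signal magnitude.
#' @return list of class `"rw_instance"`: `X` (n x p), `Y` (+-1 labels),
#'   `mu`, `support` (indices with `mu != 0`), `params`, `seed`.
#' @export
rw_simulate <- function(params, seed = 1L, tau = NULL) {
  stopifnot(inherits(params, "rw_params"))
  if (is.null(tau)) tau <- params$tau
  n <- params$n; p <- params$p
  with_seed(seed, {
    Y <- sample(c(-1, 1), n, replace = TRUE)
    mu <- numeric(p)
    S <- which(stats::runif(p) < params$eps)
    if (length(S)) mu[S] <- tau * sample(c(-1, 1), length(S), replace = TRUE)
    X <- tcrossprod(Y, mu) + matrix(stats::rnorm(n * p), n, p)
    structure(list(X = X, Y = Y, mu = mu, support = S, params = params,
                   seed = seed),
              class = "rw_instance")
  })
}

#' Rank-one planted instance with an explicit contrast vector
#'
#' Lower-level companion to [rw_simulate()] for the generic model
#' `X = Y mu' + Z`: the contrast vector is supplied directly instead of
#' drawn from the rare/weak prior. Used e.g. for eigenvector-deviation
#' diagnostics at a prescribed signal energy `||mu||^2`.
#'
#' @param n,p dimensions.
#' @param mu numeric contrast vector of length p.
#' @param seed integer seed.
#' @param noise_sd noise standard deviation (default 1; 0 gives the
#'   noiseless signal matrix).
#' @return an `"rw_instance"` (with `params = NULL`).
#' @export
rank1_instance <- function(n, p, mu, seed = 1L, noise_sd = 1) {
  stopifnot(length(mu) == p, n >= 2)
  with_seed(seed, {
    Y <- sample(c(-1, 1), n, replace = TRUE)
    X <- tcrossprod(Y, mu)
    if (noise_sd > 0) X <- X + matrix(stats::rnorm(n * p, sd = noise_sd), n, p)
    structure(list(X = X, Y = Y, mu = mu, support = which(mu != 0),
                   params = NULL, seed = seed),
              class = "rw_instance")
  })
}

#' Normalized chi-square feature scores
#'
#' `psi_j = (||x_j||^2 - n) / sqrt(2n)`: approximately standard normal for a
#' null feature and mean `sqrt(n/2) tau^2` for an influential one, the
#' screening statistic of the simplified IF-PCA.
#'
#' @param X n x p data matrix.
#' @return length-p numeric vector.
#' @export
chi2_scores <- function(X) {
  X <- as_plain_matrix(as.matrix(X))
  n <- nrow(X)
  (colSums(X^2) - n) / sqrt(2 * n)
}

# first left singular vector, via the smaller Gram matrix
first_left_sv <- function(X) {
  n <- nrow(X); p <- ncol(X)
  if (p == 1L) {
    v <- X[, 1L]
    nv <- sqrt(sum(v^2))
    if (nv == 0) return(rep(0, n))
    return(v / nv)
  }
  if (p >= n) {
    eigen(tcrossprod(X), symmetric = TRUE)$vectors[, 1L]
  } else {
    svd(X, nu = 1L, nv = 0L)$u[, 1L]
  }
}

#' Sign clustering on the first singular vector
#'
#' The simplified PCA clustering for the two-class rare/weak model: labels
#' are the signs of the entries of the first left singular vector of X
#' (zero entries map to +1 for determinism; the Hamming error is invariant
#' to a global flip).
#'
#' @param X n x p data matrix (or an `"rw_instance"`).
#' @return integer labels in \{-1, +1\}.
#' @export
simple_pca_cluster <- function(X) {
  if (inherits(X, "rw_instance")) X <- X$X
  xi <- first_left_sv(as_plain_matrix(as.matrix(X)))
  ifelse(xi >= 0, 1L, -1L)
}

#' Chi-square screened sign clustering (simplified IF-PCA)
#'
#' Selects features whose chi-square score meets the fixed threshold
#' `sqrt(2 log p)` and sign-clusters on the first left singular vector of
#' the post-selection column submatrix. No empirical-null correction and no
#' higher-criticism threshold are used in this simplified variant. An empty
#' selection falls back to full-matrix [simple_pca_cluster()] with a flag.
#'
#' @param X n x p data matrix (or an `"rw_instance"`).
#' @param threshold selection threshold (default `sqrt(2 log p)`).
#' @return list with `S_hat` (selected feature indices), `labels` (+-1),
#'   `fallback_used`.
#' @export
simple_ifpca_cluster <- function(X, threshold = NULL) {
  if (inherits(X, "rw_instance")) X <- X$X
  X <- as_plain_matrix(as.matrix(X))
  p <- ncol(X)
  stopifnot(p >= 2)
  if (is.null(threshold)) threshold <- sqrt(2 * log(p))
  psi <- chi2_scores(X)
  S_hat <- which(psi >= threshold)
  if (length(S_hat) == 0L) {
    list(S_hat = integer(0), labels = simple_pca_cluster(X),
         fallback_used = TRUE)
  } else {
    xi <- first_left_sv(X[, S_hat, drop = FALSE])
    list(S_hat = S_hat, labels = ifelse(xi >= 0, 1L, -1L),
         fallback_used = FALSE)
  }
}

#' Flip-minimized Hamming error rate
#'
#' For two-class +-1 labelings, the empirical Hamming clustering error:
#' the mismatch fraction minimized over the global sign flip of the
#' prediction. Always in `[0, 1/2]`.
#'
#' @param Y_hat,Y equal-length vectors with entries in \{-1, +1\}.
#' @return scalar error rate.
#' @export
hamming_error <- function(Y_hat, Y) {
  if (length(Y_hat) != length(Y))
    stop("length mismatch: ", length(Y_hat), " vs ", length(Y), call. = FALSE)
  if (!all(Y_hat %in% c(-1, 1)) || !all(Y %in% c(-1, 1)))
    stop("labels must be -1 or +1", call. = FALSE)
  min(mean(Y_hat != Y), mean(Y_hat != -Y))
}

#' Critical signal strength
#'
#' The piecewise signal magnitude below which all polynomial-time clustering
#' procedures fail in the rare/weak calibration:
#' `(p / (n s_p^2))^(1/4)` in the dense regime `beta < 1/2`,
#' `n^(-1/4)` for `1/2 < beta < 1 - theta/2`, and
#' `s_p^(-1/2)` in the sparsest regime `beta > 1 - theta/2`.
#' The pieces agree at both interior boundaries (evaluated by continuity),
#' and `critical_tau` equals `p^-alpha_star(beta, theta)` when the exact
#' (unrounded) power `n = p^theta` is used.
#'
#' @param params an [rw_params()], or a list with `p, theta, beta`.
#' @param exact_n use the exact power `p^theta` instead of the rounded
#'   sample size (default FALSE: matches the simulated calibration).
#' @return scalar critical strength `tau_p^*`.
#' @export
critical_tau <- function(params, exact_n = FALSE) {
  p <- params$p; theta <- params$theta; beta <- params$beta
  n <- if (exact_n) p^theta else round(p^theta)
  s_p <- p^(1 - beta)
  if (beta < 1/2) {
    (p / (n * s_p^2))^(1/4)
  } else if (beta < 1 - theta/2) {
    n^(-1/4)
  } else {
    s_p^(-1/2)
  }
}

#' Phase-transition boundary exponent
#'
#' The exponent `alpha*(beta, theta)` such that `tau_p^* = p^-alpha*`:
#' signals with `alpha < alpha*` (stronger) are clusterable in polynomial
#' time, signals with `alpha > alpha*` are not. Piecewise:
#' `(1 + theta - 2 beta)/4` for `beta < 1/2`, `theta/4` for
#' `1/2 < beta < 1 - theta/2`, `(1 - beta)/2` for `beta > 1 - theta/2`;
#' continuous at both boundaries.
#'
#' @param beta,theta exponents in (0, 1).
#' @return scalar boundary exponent.
#' @export
alpha_star <- function(beta, theta) {
  stopifnot(beta > 0, beta < 1, theta > 0, theta < 1)
  if (beta < 1/2) {
    (1 + theta - 2 * beta) / 4
  } else if (beta < 1 - theta/2) {
    theta / 4
  } else {
    (1 - beta) / 2
  }
}

#' Phase-grid experiment
#'
#' Simulates the rare/weak model over a (beta, alpha) grid and records the
#' mean (and standard error) flip-minimized Hamming error of the simplified
#' PCA and chi-square screened IF-PCA per cell. Per-cell seeds are derived
#' from the base seed by cell counter, so the grid is reproducible and each
#' cell is independent of grid ordering.
#'
#' @param theta sample-size exponent.
#' @param p dimension.
#' @param beta_grid,alpha_grid numeric grids.
#' @param reps replicates per cell (>= 1).
#' @param seed base seed.
#' @param methods subset of `c("simple_pca", "simple_ifpca")`.
#' @return data.frame with columns `beta, alpha, method, mean_error, se,
#'   reps` (`se` is NA when `reps = 1`).
#' @export
phase_grid <- function(theta, p, beta_grid, alpha_grid, reps = 20L, seed = 1L,
                       methods = c("simple_pca", "simple_ifpca")) {
  stopifnot(reps >= 1)
  methods <- match.arg(methods, several.ok = TRUE)
  out <- list(); cell <- 0L
  for (beta in beta_grid) for (alpha in alpha_grid) {
    cell <- cell + 1L
    errs <- matrix(NA_real_, reps, length(methods),
                   dimnames = list(NULL, methods))
    for (r in seq_len(reps)) {
      inst <- rw_simulate(rw_params(p, theta, beta, alpha),
                          seed = derive_seed(seed, "phase_grid",
                                             cell * 100000L + r))
      if ("simple_pca" %in% methods)
        errs[r, "simple_pca"] <- hamming_error(simple_pca_cluster(inst), inst$Y)
      if ("simple_ifpca" %in% methods)
        errs[r, "simple_ifpca"] <-
          hamming_error(simple_ifpca_cluster(inst)$labels, inst$Y)
    }
    for (m in methods) {
      out[[length(out) + 1L]] <- data.frame(
        beta = beta, alpha = alpha, method = m,
        mean_error = mean(errs[, m]),
        se = if (reps > 1) stats::sd(errs[, m]) / sqrt(reps) else NA_real_,
        reps = reps)
    }
  }
  do.call(rbind, out)
}

#' Entrywise eigenvector deviation diagnostic
#'
#' Measures how close the scaled first left singular vector of X is to the
#' true label vector: `min(||sqrt(n) xi - Y||_inf, ||sqrt(n) xi + Y||_inf)`.
#' Exactly 0 in the noiseless case; o(1) with high probability when the
#' signal energy `||mu||^2` dominates `log(n + p)`.
#'
#' @param instance an `"rw_instance"` (needs `X` and true `Y`).
#' @return scalar deviation.
#' @export
eigvec_deviation <- function(instance) {
  stopifnot(inherits(instance, "rw_instance"))
  n <- nrow(instance$X)
  xi <- first_left_sv(instance$X)
  min(max(abs(sqrt(n) * xi - instance$Y)),
      max(abs(sqrt(n) * xi + instance$Y)))
}
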