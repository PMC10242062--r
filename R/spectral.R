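#' Leading left singular vectors of a matrix
#'
#' Returns the top-r left singular vectors (columns of U in X = U D V'),
#' the subject embedding used by the spectral clustering step. Deterministic
#' up to a per-column sign for a fixed input; signs are fixed by making the
#' largest-magnitude entry of each column positive.
#'
#' @param M numeric matrix (n x p).
#' @param r number of components, at most `min(n, p)`.
#' @param source optional tag recording which matrix was embedded
#'   (`"W"`, `"X"`, `"W_IF"`, `"X_IF"`).
#' @return object of class `"pca_embedding"`: list with `vectors` (n x r,
#'   orthonormal columns), `singular_values` (nonincreasing), `source`.
#' @export
pca_embed <- function(M, r, source = "X") {
  M <- as_plain_matrix(as.matrix(M))
  check_finite_matrix(M, "embedding input")
  k <- min(dim(M))
  if (r > k) {
    warning("r = ", r, " exceeds min(dim) = ", k, "; returning ", k,
            " components")
    r <- k
  }
  sv <- svd(M, nu = r, nv = 0)
  U <- sv$u[, seq_len(r), drop = FALSE]
  # sign convention: largest-|entry| positive
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  structure(list(vectors = U, singular_values = sv$d[seq_len(r)],
                 source = source),
            class = "pca_embedding")
}

#' @export
print.pca_embedding <- function(x, ...) {
  cat(sprintf("PCA embedding of %s: %d x %d, singular values %s\n",
              x$source, nrow(x$vectors), ncol(x$vectors),
              paste(signif(x$singular_values, 4), collapse = ", ")))
  invisible(x)
}

#' Seeded best-of-restarts k-means on embedding rows
#'
#' Clusters the rows of an embedding into K groups with the classical
#' k-means, keeping the best within-cluster sum of squares over `restarts`
#' random initializations. Reproducible for a fixed seed. When fewer than K
#' distinct rows exist, the distinct rows are clustered and duplicates share
#' labels (with a warning).
#'
#' @param E a `"pca_embedding"`, a `"vae_embedding"`, or a numeric matrix of
#'   subject coordinates.
#' @param K number of clusters (K <= n).
#' @param restarts number of random starts (default 30).
#' @param seed integer seed.
#' @return integer labels in 1..K.
#' @export
kmeans_cluster <- function(E, K, restarts = 30L, seed = 1L) {
  M <- if (inherits(E, "pca_embedding")) E$vectors
       else if (inherits(E, "vae_embedding")) E$Z
       else as_plain_matrix(as.matrix(E))
  n <- nrow(M)
  stopifnot(K >= 1, K <= n)
  if (K == 1L) return(rep(1L, n))
  uq <- unique(M)
  if (nrow(uq) < K) {
    warning("fewer distinct rows (", nrow(uq), ") than clusters (", K,
            "); duplicates share labels")
    key <- apply(M, 1L, paste, collapse = "\r")
    ukey <- unique(key)
    sub <- if (nrow(uq) == 1L) rep(1L, length(ukey))
           else kmeans_cluster(uq, nrow(uq), restarts, seed)
    return(as.integer(sub[match(key, ukey)]))
  }
  with_seed(seed, {
    km <- tryCatch(
      stats::kmeans(M, centers = K, nstart = restarts, iter.max = 100L),
      error = function(e)
        stats::kmeans(M, centers = K, nstart = restarts, iter.max = 100L,
                      algorithm = "Lloyd"))
    as.integer(km$cluster)
  })
}

new_cluster_result <- function(labels, method, variant, selection, embedding,
                               seed, K) {
  structure(list(labels = as.integer(labels), method = method,
                 variant = variant, selection = selection,
                 embedding = embedding, seed = seed, K = K),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("%s clustering: n=%d, K=%d, sizes: %s\n", x$method,
              length(x$labels), x$K,
              paste(tabulate(x$labels, x$K), collapse = "/")))
  if (!is.null(x$selection))
    cat(sprintf("  IF step: %d features retained (t_HC=%.4g)\n",
                length(x$selection$retained), x$selection$t_hc))
  invisible(x)
}

#' PCA spectral clustering
#'
#' Embeds subjects with the leading left singular vectors and applies
#' k-means. The number of components follows the rank of the signal matrix
#' under the planted-mean model: K components for an unnormalized matrix,
#' K-1 for a column-standardized one (centering removes one signal
#' dimension).
#'
#' @param data an [expression_matrix()] or a `"norm_matrix"` from
#'   [normalize_columns()].
#' @param K number of clusters (>= 2).
#' @param seed integer seed for k-means.
#' @param restarts k-means restarts.
#' @return a `"cluster_result"`.
#' @export
pca_cluster <- function(data, K, seed = 1L, restarts = 30L) {
  stopifnot(K >= 2)
  normalized <- inherits(data, "norm_matrix")
  r <- if (normalized) K - 1L else K
  emb <- pca_embed(data, r, source = if (normalized) "W" else "X")
  labels <- kmeans_cluster(emb, K, restarts, derive_seed(seed, "kmeans"))
  new_cluster_result(labels, "pca", if (normalized) "W" else "X",
                     NULL, emb, seed, K)
}

#' IF-PCA clustering
#'
#' The two-stage procedure: the IF step (always on the column-standardized
#' matrix W) screens features by KS scores with Efron's correction and the
#' higher-criticism threshold; the clustering step applies k-means to the
#' first K-1 left singular vectors of the post-selection matrix. With
#' `variant = "W"` (the orthodox method) the post-selection matrix is
#' `W^IF`; with `variant = "X"` it is `X^IF`, the unnormalized columns of
#' the same retained features. Both variants use K-1 components by default
#' (configurable through `n_components`).
#'
#' @param X an [expression_matrix()] (unnormalized).
#' @param K number of clusters (>= 2).
#' @param variant `"W"` or `"X"`: which matrix feeds the clustering step.
#' @param seed integer seed.
#' @param restarts k-means restarts.
#' @param n_components components for the post-selection SVD (default K-1).
#' @param min_retained minimum retained features (default K-1).
#' @return a `"cluster_result"` with the `"if_selection"` attached.
#' @export
if_pca <- function(X, K, variant = c("W", "X"), seed = 1L, restarts = 30L,
                   n_components = K - 1L, min_retained = K - 1L) {
  variant <- match.arg(variant)
  stopifnot(K >= 2)
  X <- as.matrix(X)
  W <- normalize_columns(X)
  sel <- select_features(W, min_retained = min_retained)
  keepW <- sel$retained
  if (variant == "W") {
    sub <- as_plain_matrix(W)[, keepW, drop = FALSE]
    src <- "W_IF"
  } else {
    # map retained W columns back to original X columns (constant columns
    # may have been dropped during normalization)
    keepX <- attr(W, "source_feature_index")[keepW]
    sub <- as_plain_matrix(X)[, keepX, drop = FALSE]
    src <- "X_IF"
  }
  emb <- pca_embed(sub, min(n_components, min(dim(sub))), source = src)
  labels <- kmeans_cluster(emb, K, restarts, derive_seed(seed, "kmeans"))
  new_cluster_result(labels, "ifpca", variant, sel, emb, seed, K)
}
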