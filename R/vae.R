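#' VAE training configuration
#'
#' Architecture and optimization settings for the variational autoencoder:
#' one ReLU hidden layer in the encoder, a Gaussian latent layer
#' (mean + log-variance heads), one hidden layer in the decoder with a
#' sigmoid output; trained by minibatch stochastic gradient descent on the
#' negative ELBO (Bernoulli cross-entropy reconstruction + KL to a standard
#' normal prior). Inputs are min-max scaled to \[0, 1\] per feature before
#' training, matching the sigmoid output range.
#'
#' @param latent_dim latent dimension d (default 25).
#' @param hidden_width hidden layer width (default 128).
#' @param epochs training epochs (default 100).
#' @param n_batches minibatches per epoch (default 50; batch size is
#'   `ceiling(n / n_batches)`).
#' @param learning_rate SGD step size (default 0.0005).
#' @param optimizer `"sgd"` (plain, the default) or `"adam"`.
#' @param seed integer seed governing initialization, shuffling and the
#'   reparameterization noise.
#' @return a list of class `"vae_config"`.
#' @export
vae_config <- function(latent_dim = 25L, hidden_width = 128L, epochs = 100L,
                       n_batches = 50L, learning_rate = 5e-4,
                       optimizer = c("sgd", "adam"), seed = 1L) {
  optimizer <- match.arg(optimizer)
  stopifnot(latent_dim >= 1, hidden_width >= 1, epochs >= 1, n_batches >= 1,
            learning_rate > 0)
  structure(list(latent_dim = as.integer(latent_dim),
                 hidden_width = as.integer(hidden_width),
                 epochs = as.integer(epochs),
                 n_batches = as.integer(n_batches),
                 learning_rate = learning_rate, optimizer = optimizer,
                 seed = as.integer(seed)),
            class = "vae_config")
}

glorot <- function(fan_in, fan_out) {
  l <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -l, l), fan_in, fan_out)
}

sigmoid <- function(x) 1 / (1 + exp(-pmin(pmax(x, -30), 30)))

#' Train a variational autoencoder
#'
#' Fits the one-hidden-layer VAE described in [vae_config()] and returns the
#' encoder means as the subject embedding. The implementation is a compact
#' dense-network reference in base R (hand-derived gradients); it is meant
#' for the moderate problem sizes this package targets, not for GPU-scale
#' training.
#'
#' @param M numeric n x p matrix (any scale; min-max scaled internally).
#' @param config a [vae_config()].
#' @return object of class `"vae_embedding"`: list with `Z` (n x d encoder
#'   means), `loss_trace` (mean per-subject negative ELBO per epoch),
#'   `config`.
#' @export
train_vae <- function(M, config = vae_config()) {
  stopifnot(inherits(config, "vae_config"))
  M <- as_plain_matrix(as.matrix(M))
  check_finite_matrix(M, "VAE input")
  n <- nrow(M); p <- ncol(M)
  # per-feature min-max scaling to [0, 1]; constant features map to 0.5
  lo <- apply(M, 2L, min); hi <- apply(M, 2L, max)
  rng <- hi - lo
  X01 <- sweep(sweep(M, 2L, lo), 2L, ifelse(rng > 0, rng, 1), "/")
  X01[, rng == 0] <- 0.5
  d <- config$latent_dim; H <- config$hidden_width
  lr <- config$learning_rate
  adam <- config$optimizer == "adam"
  with_seed(config$seed, {
    par <- list(W1 = glorot(p, H), b1 = numeric(H),
                Wm = glorot(H, d), bm = numeric(d),
                Wv = glorot(H, d), bv = numeric(d),
                W4 = glorot(d, H), b4 = numeric(H),
                W5 = glorot(H, p), b5 = numeric(p))
    if (adam) {
      m1 <- lapply(par, function(w) w * 0)
      m2 <- lapply(par, function(w) w * 0)
      t_step <- 0
    }
    bsz <- ceiling(n / config$n_batches)
    trace <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_n <- 0
      for (b in seq_len(config$n_batches)) {
        start <- 1 + (b - 1) * bsz
        if (start > n) break
        idx <- ord[seq.int(start, min(b * bsz, n))]
        x <- X01[idx, , drop = FALSE]
        B <- nrow(x)
        # forward
        a1 <- sweep(x %*% par$W1, 2L, par$b1, "+"); h1 <- pmax(a1, 0)
        mu <- sweep(h1 %*% par$Wm, 2L, par$bm, "+")
        lv <- pmin(pmax(sweep(h1 %*% par$Wv, 2L, par$bv, "+"), -10), 10)
        eps <- matrix(stats::rnorm(B * d), B, d)
        z <- mu + eps * exp(0.5 * lv)
        a4 <- sweep(z %*% par$W4, 2L, par$b4, "+"); h2 <- pmax(a4, 0)
        o <- sigmoid(sweep(h2 %*% par$W5, 2L, par$b5, "+"))
        oc <- pmin(pmax(o, 1e-7), 1 - 1e-7)
        bce <- -sum(x * log(oc) + (1 - x) * log(1 - oc))
        kl <- -0.5 * sum(1 + lv - mu^2 - exp(lv))
        if (!is.finite(bce + kl))
          stop("training diverged: non-finite loss at epoch ", ep, call. = FALSE)
        ep_loss <- ep_loss + bce + kl; ep_n <- ep_n + B
        # backward (gradients of mean-per-subject loss)
        go <- (o - x) / B                          # d(BCE)/d(pre-sigmoid)
        gW5 <- crossprod(h2, go); gb5 <- colSums(go)
        gh2 <- tcrossprod(go, par$W5) * (a4 > 0)
        gW4 <- crossprod(z, gh2); gb4 <- colSums(gh2)
        gz <- tcrossprod(gh2, par$W4)
        gmu <- gz + mu / B                         # + d(KL)/d(mu)
        glv <- gz * eps * 0.5 * exp(0.5 * lv) + 0.5 * (exp(lv) - 1) / B
        gh1 <- (tcrossprod(gmu, par$Wm) + tcrossprod(glv, par$Wv)) * (a1 > 0)
        grad <- list(W1 = crossprod(x, gh1), b1 = colSums(gh1),
                     Wm = crossprod(h1, gmu), bm = colSums(gmu),
                     Wv = crossprod(h1, glv), bv = colSums(glv),
                     W4 = gW4, b4 = gb4, W5 = gW5, b5 = gb5)
        if (adam) {
          t_step <- t_step + 1
          for (k in names(par)) {
            m1[[k]] <- 0.9 * m1[[k]] + 0.1 * grad[[k]]
            m2[[k]] <- 0.999 * m2[[k]] + 0.001 * grad[[k]]^2
            mh <- m1[[k]] / (1 - 0.9^t_step)
            vh <- m2[[k]] / (1 - 0.999^t_step)
            par[[k]] <- par[[k]] - lr * mh / (sqrt(vh) + 1e-8)
          }
        } else {
          for (k in names(par)) par[[k]] <- par[[k]] - lr * grad[[k]]
        }
      }
      trace[ep] <- ep_loss / ep_n
    }
    a1 <- sweep(X01 %*% par$W1, 2L, par$b1, "+"); h1 <- pmax(a1, 0)
    Z <- sweep(h1 %*% par$Wm, 2L, par$bm, "+")
    structure(list(Z = Z, loss_trace = trace, config = config),
              class = "vae_embedding")
  })
}

#' @export
print.vae_embedding <- function(x, ...) {
  cat(sprintf("VAE embedding: %d x %d, final loss %.4g\n",
              nrow(x$Z), ncol(x$Z), utils::tail(x$loss_trace, 1)))
  invisible(x)
}

#' VAE clustering
#'
#' Trains the VAE on the given matrix and applies k-means to the rows of the
#' latent-mean embedding.
#'
#' @param M numeric matrix (normalized or not; min-max scaling is applied
#'   internally either way).
#' @param K number of clusters.
#' @param config a [vae_config()].
#' @param restarts k-means restarts.
#' @return a `"cluster_result"`.
#' @export
vae_cluster <- function(M, K, config = vae_config(), restarts = 30L) {
  stopifnot(K >= 1)
  emb <- train_vae(M, config)
  labels <- kmeans_cluster(emb, K, restarts,
                           derive_seed(config$seed, "kmeans"))
  variant <- if (inherits(M, "norm_matrix")) "W" else "X"
  new_cluster_result(labels, "vae", variant, NULL, emb, config$seed, K)
}

#' IF-VAE clustering
#'
#' Same IF step as [if_pca()] (KS scores, Efron correction,
#' higher-criticism threshold, always on the column-standardized matrix W),
#' then VAE embedding + k-means on the post-selection matrix: `W^IF` for
#' `variant = "W"`, `X^IF` for `variant = "X"`.
#'
#' @param X an [expression_matrix()] (unnormalized).
#' @param K number of clusters (>= 2).
#' @param variant `"W"` or `"X"`.
#' @param config a [vae_config()].
#' @param restarts k-means restarts.
#' @param min_retained minimum retained features (default K-1).
#' @return a `"cluster_result"` with the `"if_selection"` attached.
#' @export
if_vae <- function(X, K, variant = c("W", "X"), config = vae_config(),
                   restarts = 30L, min_retained = K - 1L) {
  variant <- match.arg(variant)
  stopifnot(K >= 2)
  X <- as.matrix(X)
  W <- normalize_columns(X)
  sel <- select_features(W, min_retained = min_retained)
  sub <- if (variant == "W") {
    as_plain_matrix(W)[, sel$retained, drop = FALSE]
  } else {
    keepX <- attr(W, "source_feature_index")[sel$retained]
    as_plain_matrix(X)[, keepX, drop = FALSE]
  }
  emb <- train_vae(sub, config)
  labels <- kmeans_cluster(emb, K, restarts,
                           derive_seed(config$seed, "kmeans"))
  res <- new_cluster_result(labels, "ifvae", variant, sel, emb,
                            config$seed, K)
  res
}
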