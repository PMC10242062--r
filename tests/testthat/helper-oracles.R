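# Independent oracles used across the test files. Each one computes the
# quantity from its definition by brute force, without reusing the package's
# computational shortcuts.

# sup_t |F_n(t) - F(t)| of the studentized sample against the standard
# normal, evaluated over a dense grid augmented with the jump points of the
# empirical CDF (and points just left of them), where the supremum of a
# step-function difference is attained. Exact to ~1e-9.
oracle_ks <- function(z) {
  n <- length(z)
  u <- (z - mean(z)) / sd(z)
  Fn <- stats::ecdf(u)
  grid <- sort(c(seq(min(u) - 2, max(u) + 2, length.out = 1e5),
                 u, u - 1e-9))
  sqrt(n) * max(abs(Fn(grid) - pnorm(grid)))
}

# exhaustive scan of the higher-criticism functional over the admissible
# set, straight from the definition
oracle_hct <- function(pvalues, n) {
  p <- length(pvalues)
  ps <- sort(pvalues)
  j <- seq_len(p)
  hc <- sqrt(p) * (j / p - ps) / sqrt(pmax(sqrt(n) * (j / p - ps), 0) + j / p)
  adm <- which(ps > log(p) / p & j < p / 2)
  fallback <- length(adm) == 0
  cand <- if (fallback) which(j < p / 2) else adm
  best <- cand[1]
  for (k in cand) if (hc[k] > hc[best]) best <- k
  list(j_hat = best, t_hc = ps[best], fallback = fallback)
}

# minimum mismatch count over every permutation of cluster identities,
# enumerated explicitly
oracle_clustering_error <- function(y_hat, y, K = max(y_hat, y)) {
  perms <- perms_of(seq_len(K))
  best <- Inf
  for (i in seq_len(nrow(perms)))
    best <- min(best, sum(perms[i, ][y_hat] != y))
  best
}

perms_of <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1L, 1L))
  out <- NULL
  for (i in seq_along(v)) {
    sub <- perms_of(v[-i])
    out <- rbind(out, cbind(v[i], sub))
  }
  out
}

# flip-minimized Hamming error by enumeration of the two sign assignments
oracle_hamming <- function(y_hat, y) {
  min(mean(y_hat != y), mean((-y_hat) != y))
}

# ARI from first principles via the pair-counting definition:
# classify all n(n-1)/2 subject pairs as together/apart in each partition
oracle_ari_pairs <- function(y1, y2) {
  n <- length(y1)
  a <- b <- c2 <- d <- 0
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    s1 <- y1[i] == y1[j]; s2 <- y2[i] == y2[j]
    if (s1 && s2) a <- a + 1
    else if (s1 && !s2) b <- b + 1
    else if (!s1 && s2) c2 <- c2 + 1
    else d <- d + 1
  }
  tot <- a + b + c2 + d
  exp_a <- (a + b) * (a + c2) / tot
  max_a <- ((a + b) + (a + c2)) / 2
  if (max_a == exp_a) return(1)
  (a - exp_a) / (max_a - exp_a)
}

# two-class data whose useful columns are strongly bimodal mixtures --
# the marginal signal shape the KS screen is designed to pick up
planted_two_class <- function(n, p, n_useful, contrast, seed) {
  sim <- generate_planted_data(n = n, p = p, K = 2, n_useful = n_useful,
                               effect_size = contrast, noise_sd = 1,
                               seed = seed)
  list(X = sim$X, labels = sim$labels, support = sim$design$support)
}
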