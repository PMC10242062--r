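test_that("calibration derives n, eps, tau, s_p from the exponents", {
  prm <- rw_params(10000, theta = 0.6, beta = 0.3, alpha = 0.15)
  expect_identical(prm$n, 251L)                 # round(10000^0.6)
  expect_equal(prm$eps, 10000^-0.3)
  expect_equal(prm$tau, 10000^-0.15)
  expect_equal(prm$s_p, 10000^0.7)
  expect_error(rw_params(4, 0.1, 0.3, 0.2), "infeasible")
})

test_that("simulated instances match the model: support size, labels, noise", {
  prm <- rw_params(2000, 0.6, 0.4, 0.2)
  sizes <- sapply(1:200, function(s) length(rw_simulate(prm, seed = s)$support))
  expect_lt(abs(mean(sizes) - 2000 * prm$eps),
            3 * sqrt(2000 * prm$eps * (1 - prm$eps) / 200))
  inst <- rw_simulate(prm, seed = 1)
  expect_true(all(inst$Y %in% c(-1, 1)))
  expect_true(all(abs(inst$mu[inst$support]) == prm$tau))
  expect_true(all(inst$mu[-inst$support] == 0))
  # noise variance near 1
  Z <- inst$X - tcrossprod(inst$Y, inst$mu)
  expect_lt(abs(var(as.numeric(Z)) - 1), 3 * sqrt(2 / length(Z)) + 0.01)
  expect_identical(rw_simulate(prm, seed = 9)$X, rw_simulate(prm, seed = 9)$X)
})

test_that("chi-square scores are centered for null features and shifted for useful ones", {
  n <- 100
  X <- matrix(rnorm(n * 10000), n, 10000)
  psi <- chi2_scores(X)
  expect_lt(abs(mean(psi)), 3 / sqrt(10000) * 1.5)
  expect_lt(abs(sd(psi) - 1), 0.05)
  # exactly zero when the column norm equals n
  Xc <- matrix(1, 4, 2)                       # ||x_j||^2 = 4 = n
  expect_equal(chi2_scores(Xc), c(0, 0))
  # useful columns: mean near sqrt(n/2) tau^2
  tau <- 0.5
  set.seed(3)
  reps <- replicate(2000, {
    y <- sample(c(-1, 1), n, TRUE)
    chi2_scores(matrix(y * tau + rnorm(n), n, 1))
  })
  expect_lt(abs(mean(reps) - sqrt(n / 2) * tau^2), 3 * sd(reps) / sqrt(2000))
})

test_that("sign clustering recovers labels perfectly without noise", {
  prm <- rw_params(500, 0.6, 0.3, 0.1)
  set.seed(4)
  mu <- numeric(500); S <- sample(500, 60); mu[S] <- prm$tau
  inst <- rank1_instance(n = 50, p = 500, mu = mu, seed = 2, noise_sd = 0)
  expect_equal(hamming_error(simple_pca_cluster(inst), inst$Y), 0)
  ifp <- simple_ifpca_cluster(inst$X, threshold = 0)
  expect_equal(hamming_error(ifp$labels, inst$Y), 0)
})

test_that("pure noise gives near-chance error for any clustering", {
  prm <- rw_params(1000, 0.6, 0.3, 0.2)
  errs <- sapply(1:10, function(s) {
    inst <- rw_simulate(prm, seed = s, tau = 0)        # tau -> 0 limit
    hamming_error(simple_pca_cluster(inst), inst$Y)
  })
  expect_gt(mean(errs), 0.35)
  expect_lte(max(errs), 0.5)
})

test_that("empty chi-square selection falls back to full-matrix PCA with a flag", {
  prm <- rw_params(800, 0.6, 0.4, 0.3)
  inst <- rw_simulate(prm, seed = 5, tau = 0)
  ifp <- simple_ifpca_cluster(inst$X, threshold = 50)  # nothing passes
  expect_true(ifp$fallback_used)
  expect_length(ifp$S_hat, 0)
  expect_identical(ifp$labels, simple_pca_cluster(inst$X))
})

test_that("flip-minimized Hamming error: hand cases, exhaustive oracle, invariances", {
  expect_equal(hamming_error(c(1, 1, -1, -1), c(-1, -1, 1, 1)), 0)
  expect_equal(hamming_error(c(1, 1, 1, -1), c(1, 1, -1, -1)), 0.25)
  grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), 8)))
  set.seed(6)
  y <- sample(c(-1, 1), 8, TRUE)
  for (i in seq_len(nrow(grid))) {
    yh <- grid[i, ]
    expect_equal(hamming_error(yh, y), oracle_hamming(yh, y))
    expect_equal(hamming_error(yh, y), hamming_error(-yh, y))
    expect_equal(hamming_error(yh, y), hamming_error(yh, -y))
  }
  expect_error(hamming_error(c(1, -1), c(1, -1, 1)), "length")
  expect_error(hamming_error(c(1, 2), c(1, -1)), "-1 or \\+1")
})

test_that("critical strength and boundary exponent: values, continuity, consistency", {
  # representative interior points of the three regimes
  expect_equal(critical_tau(rw_params(10000, 0.6, 0.55, 0.2)), 251^(-1/4))
  expect_equal(alpha_star(0.3, 0.6), 0.25)
  expect_equal(alpha_star(0.55, 0.6), 0.15)
  expect_equal(alpha_star(0.9, 0.6), 0.05)
  for (theta in seq(0.2, 0.8, by = 0.1)) {
    eps <- 1e-9
    # continuity at beta = 1/2
    expect_lt(abs(alpha_star(0.5 - eps, theta) - alpha_star(0.5 + eps, theta)),
              1e-8)
    # continuity at beta = 1 - theta/2
    b <- 1 - theta / 2
    expect_lt(abs(alpha_star(b - eps, theta) - alpha_star(b + eps, theta)),
              1e-8)
    # tau* = p^-alpha* when exact powers are used
    for (beta in c(0.3, 0.55, 0.9)) {
      if (beta >= b - 1e-6 && beta <= b + 1e-6) next
      prm2 <- list(p = 5000, theta = theta, beta = beta)
      expect_equal(log(critical_tau(prm2, exact_n = TRUE)) / log(5000),
                   -alpha_star(beta, theta), tolerance = 1e-12)
    }
  }
})

test_that("phase grid reports per-cell means, SEs, and is monotone in alpha", {
  g <- phase_grid(theta = 0.6, p = 800, beta_grid = 0.3,
                  alpha_grid = c(0.05, 0.45), reps = 8, seed = 1,
                  methods = "simple_pca")
  expect_equal(nrow(g), 2L)
  expect_true(all(c("beta", "alpha", "method", "mean_error", "se", "reps")
                  %in% names(g)))
  # error increases from deep possibility to deep impossibility
  expect_lt(g$mean_error[g$alpha == 0.05], g$mean_error[g$alpha == 0.45])
  g1 <- phase_grid(0.6, 500, 0.3, 0.2, reps = 1, seed = 2)
  expect_true(all(is.na(g1$se)))
  # per-cell seeding: same seed reproduces the grid
  g2 <- phase_grid(theta = 0.6, p = 800, beta_grid = 0.3,
                   alpha_grid = c(0.05, 0.45), reps = 8, seed = 1,
                   methods = "simple_pca")
  expect_identical(g, g2)
})

test_that("null chi-square selections at sqrt(2 log p) match the Poisson prediction", {
  p <- 2000; n <- 100
  thr <- sqrt(2 * log(p))
  counts <- sapply(1:100, function(s) {
    set.seed(s)
    sum(chi2_scores(matrix(rnorm(n * p), n, p)) >= thr)
  })
  # exact null of the score: ||x_j||^2 ~ chi^2_n, whose right tail at this
  # threshold is noticeably heavier than the normal approximation at n = 100
  lambda <- p * pchisq(n + thr * sqrt(2 * n), df = n, lower.tail = FALSE)
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 100) + 0.05)
})

test_that("eigenvector deviation is zero without noise and shrinks with signal energy", {
  n <- 80; p <- 400
  mk <- function(energy, seed, noise) {
    s <- 40
    mu <- c(rep(sqrt(energy / s), s), numeric(p - s))
    rank1_instance(n, p, mu, seed = seed, noise_sd = noise)
  }
  expect_equal(eigvec_deviation(mk(30, 1, 0)), 0, tolerance = 1e-8)
  meds <- sapply(c(10, 40, 160), function(en) {
    median(sapply(1:10, function(s) eigvec_deviation(mk(en, s, 1))))
  })
  expect_true(all(diff(meds) < 0.05))          # median non-increasing (slack)
})
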