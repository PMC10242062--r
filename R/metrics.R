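# ---- optimal cluster matching -------------------------------------------

# exhaustive minimum mismatches over all permutations of cluster identities
match_exhaustive <- function(tab) {
  K <- nrow(tab)
  total <- sum(tab)
  perms <- all_permutations(K)
  best <- Inf
  for (i in seq_len(nrow(perms))) {
    agree <- sum(tab[cbind(seq_len(K), perms[i, ])])
    best <- min(best, total - agree)
  }
  best
}

all_permutations <- function(K) {
  if (K == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(K - 1L)
  out <- matrix(0L, 0L, K)
  for (pos in seq_len(K)) {
    ins <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], K,
                 sub[, seq.int(pos, K - 1L)[seq_len(K - pos)], drop = FALSE])
    out <- rbind(out, ins)
  }
  out
}

# Hungarian algorithm (shortest augmenting path with dual potentials) for a
# square cost matrix; returns the minimum total assignment cost. Columns are
# offset by one so that index 1 plays the virtual "column 0" of the classic
# formulation; rows likewise (u[1] is the virtual row's potential).
hungarian_cost <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  match_row <- integer(n + 1)        # row matched to column j-1 (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    match_row[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- match_row[j0]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n) + 1L) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0 + 1L] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          u[match_row[j] + 1L] <- u[match_row[j] + 1L] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (match_row[j0] == 0L) break
    }
    repeat {                          # augment along the recorded path
      j1 <- way[j0]
      match_row[j0] <- match_row[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  total <- 0
  for (j in seq_len(n) + 1L)
    if (match_row[j] > 0L) total <- total + cost[match_row[j], j - 1L]
  total
}

#' Permutation-minimized clustering error
#'
#' Number of misclustered subjects, minimized over all permutations of the
#' cluster identities of the prediction. Exhaustive enumeration for
#' `K <= 6`; optimal assignment (Hungarian algorithm) for larger K.
#'
#' @param Y_hat,Y equal-length label vectors with values in 1..K.
#' @return integer mismatch count.
#' @export
clustering_error <- function(Y_hat, Y) {
  if (length(Y_hat) != length(Y))
    stop("length mismatch", call. = FALSE)
  Y_hat <- as.integer(Y_hat); Y <- as.integer(Y)
  K <- max(Y_hat, Y)
  if (any(c(Y_hat, Y) < 1L))
    stop("labels must be positive integers in 1..K", call. = FALSE)
  tab <- table(factor(Y_hat, levels = seq_len(K)),
               factor(Y, levels = seq_len(K)))
  tab <- matrix(as.numeric(tab), K, K)
  if (K <= 6L) as.integer(match_exhaustive(tab))
  else as.integer(sum(tab) + hungarian_cost(-tab))
}

#' Clustering accuracy
#'
#' Fraction of correctly clustered subjects under the optimal cluster
#' matching: `1 - clustering_error / n`.
#'
#' @inheritParams clustering_error
#' @return scalar in `[0, 1]`.
#' @export
accuracy <- function(Y_hat, Y) {
  1 - clustering_error(Y_hat, Y) / length(Y)
}

#' Adjusted Rand index
#'
#' Chance-corrected partition agreement computed from the contingency
#' table: `(sum_ij C(n_ij,2) - E) / (max - E)` with the usual expected-index
#' correction. 1 for identical partitions; about 0 for independent random
#' partitions; can be negative.
#'
#' @param Y_hat,Y equal-length label vectors (any discrete coding).
#' @return scalar `<= 1`.
#' @export
adjusted_rand_index <- function(Y_hat, Y) {
  if (length(Y_hat) != length(Y)) stop("length mismatch", call. = FALSE)
  n <- length(Y)
  tab <- table(Y_hat, Y)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  denom <- (a + b) / 2 - expected
  if (denom == 0) return(1)           # both partitions trivial/identical
  (sum_ij - expected) / denom
}

#' Midrank assignment with ties
#'
#' Ranks a vector of method scores so that tied values share the mean of
#' the ranks they occupy (two tied best methods both get 1.5); the ranks of
#' m methods always sum to `m (m + 1) / 2`. Direction `"lower_better"`
#' ranks the smallest value 1 (errors); `"higher_better"` ranks the largest
#' value 1 (accuracies).
#'
#' @param values numeric vector, length >= 2.
#' @param direction `"lower_better"` or `"higher_better"`.
#' @return numeric midranks.
#' @export
rank_with_ties <- function(values, direction = c("lower_better",
                                                 "higher_better")) {
  direction <- match.arg(direction)
  stopifnot(length(values) >= 2)
  v <- if (direction == "lower_better") values else -values
  rank(v, ties.method = "average")
}

#' Within-data-set regret
#'
#' Rescales method scores to `[0, 1]` within one data set:
#' `(e - e_min) / (e_max - e_min)` for errors (best method 0, worst 1),
#' and symmetrically `(a_max - a) / (a_max - a_min)` for accuracies. When
#' all methods tie, all regrets are 0.
#'
#' @inheritParams rank_with_ties
#' @return numeric regrets in `[0, 1]`.
#' @export
regret <- function(values, direction = c("lower_better", "higher_better")) {
  direction <- match.arg(direction)
  stopifnot(length(values) >= 2)
  lo <- min(values); hi <- max(values)
  if (hi == lo) return(rep(0, length(values)))
  if (direction == "lower_better") (values - lo) / (hi - lo)
  else (hi - values) / (hi - lo)
}

#' Rank/regret summary across data sets
#'
#' Aggregates a data-sets x methods score table the way multi-data-set
#' benchmark comparisons are summarized: per-row midranks and regrets over
#' the included methods, then per-method means and standard deviations.
#' Methods listed in `exclude` are dropped before ranking (mirroring the
#' exclusion of a method that returns NA on some data set); any remaining
#' missing cell is an error.
#'
#' @param table numeric matrix or data.frame, rows = data sets,
#'   columns = methods.
#' @param direction `"lower_better"` for error tables, `"higher_better"`
#'   for accuracy tables.
#' @param exclude character vector of method (column) names to drop.
#' @param sd_denominator `"n-1"` (sample, default) or `"n"`.
#' @return data.frame with one row per method: `rank_mean, rank_sd,
#'   regret_mean, regret_sd`.
#' @export
summarize_table <- function(table, direction = c("lower_better",
                                                 "higher_better"),
                            exclude = character(0),
                            sd_denominator = c("n-1", "n")) {
  direction <- match.arg(direction)
  sd_denominator <- match.arg(sd_denominator)
  M <- as.matrix(table)
  if (length(exclude))
    M <- M[, setdiff(colnames(M), exclude), drop = FALSE]
  if (any(is.na(M))) {
    bad <- colnames(M)[colSums(is.na(M)) > 0]
    stop("missing cells for included method(s): ",
         paste(bad, collapse = ", "), "; exclude them explicitly",
         call. = FALSE)
  }
  ranks <- t(apply(M, 1L, rank_with_ties, direction = direction))
  regrets <- t(apply(M, 1L, regret, direction = direction))
  sdfun <- if (sd_denominator == "n-1") stats::sd
           else function(x) sqrt(mean((x - mean(x))^2))
  data.frame(method = colnames(M),
             rank_mean = colMeans(ranks),
             rank_sd = apply(ranks, 2L, sdfun),
             regret_mean = colMeans(regrets),
             regret_sd = apply(regrets, 2L, sdfun),
             row.names = NULL)
}
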