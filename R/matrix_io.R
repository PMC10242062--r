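#' Construct an expression matrix
#'
#' An expression matrix is an n x p numeric matrix with subjects (samples,
#' cells) in rows and features (genes, probes) in columns. Subject and
#' feature identifiers are carried as dimnames and must be unique; all
#' entries must be finite (missing values are rejected, not imputed).
#'
#' @param values numeric n x p matrix.
#' @param subject_ids character vector of length n (defaults to existing
#'   rownames, or `s1..sn`).
#' @param feature_ids character vector of length p (defaults to existing
#'   colnames, or `f1..fp`).
#' @return the validated matrix, with class `"expr_matrix"` prepended.
#' @export
expression_matrix <- function(values, subject_ids = NULL, feature_ids = NULL) {
  check_finite_matrix(values, "expression matrix")
  n <- nrow(values); p <- ncol(values)
  if (n == 0L || p == 0L)
    stop("expression matrix must have at least one subject and one feature",
         call. = FALSE)
  if (is.null(subject_ids)) subject_ids <- rownames(values)
  if (is.null(subject_ids)) subject_ids <- paste0("s", seq_len(n))
  if (is.null(feature_ids)) feature_ids <- colnames(values)
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(p))
  if (length(subject_ids) != n)
    stop("dimension error: ", length(subject_ids), " subject ids for ",
         n, " rows", call. = FALSE)
  if (length(feature_ids) != p)
    stop("dimension error: ", length(feature_ids), " feature ids for ",
         p, " columns", call. = FALSE)
  if (anyDuplicated(subject_ids)) stop("subject ids must be unique", call. = FALSE)
  if (anyDuplicated(feature_ids)) stop("feature ids must be unique", call. = FALSE)
  dimnames(values) <- list(as.character(subject_ids), as.character(feature_ids))
  class(values) <- c("expr_matrix", class(values))
  values
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d subjects x %d features\n", nrow(x), ncol(x)))
  invisible(x)
}

# strip the S3 tag, keep dimnames
as_plain_matrix <- function(X) {
  class(X) <- "matrix"
  attr(X, "dropped_features") <- NULL
  attr(X, "source_feature_index") <- NULL
  X
}

detect_sep <- function(header_line) {
  if (grepl("\t", header_line)) "\t" else ","
}

#' Read an expression matrix from disk
#'
#' Two on-disk layouts are supported:
#' \describe{
#'   \item{`dense`}{delimited text (tab or comma, auto-detected from the
#'     header line): first row feature identifiers, first column subject
#'     identifiers.}
#'   \item{`mtx`}{MatrixMarket coordinate format, with `features.tsv` and
#'     `barcodes.tsv` sidecar files (one identifier per line) next to the
#'     matrix file, as written by common single-cell pipelines. These files
#'     are gene-by-cell, so pass `orientation = "features_by_subjects"`.}
#' }
#' Matrices are always returned in subjects-by-features orientation,
#' transposing when `orientation = "features_by_subjects"`.
#'
#' @param path path to the matrix file.
#' @param format `"dense"` or `"mtx"`.
#' @param orientation orientation of the file on disk.
#' @return an [expression_matrix()].
#' @export
read_matrix <- function(path, format = c("dense", "mtx"),
                        orientation = c("subjects_by_features",
                                        "features_by_subjects")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "dense") {
    header <- readLines(path, n = 1L)
    if (!nzchar(header))
      stop("parse error at line 1 of ", path, ": empty header", call. = FALSE)
    sep <- detect_sep(header)
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                            check.names = FALSE, comment.char = "",
                            quote = "\"", stringsAsFactors = FALSE)
    M <- as.matrix(df)
    if (!is.numeric(M))
      stop("parse error in ", path, ": non-numeric entries found", call. = FALSE)
    row_ids <- rownames(M); col_ids <- colnames(M)
  } else {
    dir <- dirname(path)
    feat_file <- file.path(dir, "features.tsv")
    bc_file <- file.path(dir, "barcodes.tsv")
    if (!file.exists(feat_file) || !file.exists(bc_file))
      stop("mtx sidecar files features.tsv/barcodes.tsv not found in ", dir,
           call. = FALSE)
    Msp <- Matrix::readMM(path)
    M <- as.matrix(Msp)
    feats <- readLines(feat_file)
    bcs <- readLines(bc_file)
    # features.tsv may have extra columns (id, symbol, type); keep column 1
    feats <- vapply(strsplit(feats, "\t"), `[`, character(1), 1L)
    bcs <- vapply(strsplit(bcs, "\t"), `[`, character(1), 1L)
    if (length(feats) != nrow(M))
      stop("dimension error: ", length(feats), " feature ids for ",
           nrow(M), " matrix rows", call. = FALSE)
    if (length(bcs) != ncol(M))
      stop("dimension error: ", length(bcs), " barcode ids for ",
           ncol(M), " matrix columns", call. = FALSE)
    row_ids <- feats; col_ids <- bcs
  }
  if (any(!is.finite(M)))
    stop("validation error: ", path, " contains NaN/Inf entries", call. = FALSE)
  if (orientation == "features_by_subjects") {
    M <- t(M)
    tmp <- row_ids; row_ids <- col_ids; col_ids <- tmp
  }
  expression_matrix(M, subject_ids = row_ids, feature_ids = col_ids)
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_matrix()]: `read_matrix(write_matrix(X, path, fmt), fmt)`
#' reproduces `X` up to float formatting (15 significant digits).
#'
#' @param X an [expression_matrix()] (or plain numeric matrix with dimnames).
#' @param path output path; for `"mtx"`, sidecar `features.tsv` and
#'   `barcodes.tsv` files are written next to it and the matrix is stored
#'   gene-by-cell (features in rows).
#' @param format `"dense"` (tab-delimited) or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(X, path, format = c("dense", "mtx")) {
  format <- match.arg(format)
  X <- expression_matrix(as_plain_matrix(as.matrix(X)))
  if (format == "dense") {
    df <- as.data.frame(as_plain_matrix(X))
    out <- data.frame(subject_id = rownames(X), df, check.names = FALSE)
    ok <- tryCatch({
      utils::write.table(out, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      TRUE
    }, error = function(e) e, warning = function(w) w)
    if (!isTRUE(ok)) stop("I/O error writing ", path, ": ",
                          conditionMessage(ok), call. = FALSE)
  } else {
    dir <- dirname(path)
    Msp <- Matrix::Matrix(t(as_plain_matrix(X)), sparse = TRUE)
    ok <- tryCatch({
      Matrix::writeMM(Msp, path)
      writeLines(colnames(X), file.path(dir, "features.tsv"))
      writeLines(rownames(X), file.path(dir, "barcodes.tsv"))
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop("I/O error writing ", path, ": ",
                          conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}

#' Read a label file
#'
#' One label per line, aligned to subject order of the companion matrix.
#'
#' @param path file path.
#' @param n optional expected length (checked when given).
#' @return character vector of labels.
#' @export
read_labels <- function(path, n = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lab <- readLines(path)
  lab <- lab[nzchar(lab)]
  if (!is.null(n) && length(lab) != n)
    stop("dimension error: ", length(lab), " labels for ", n, " subjects",
         call. = FALSE)
  lab
}

#' Column-standardize an expression matrix
#'
#' Centers every feature to mean 0 and scales it to standard deviation 1,
#' the normalization applied before the IF step. The standard deviation
#' convention is the sample one (denominator n-1) by default; since a common
#' rescaling of a column does not change its studentized values, the choice
#' only matters for exact reproduction of intermediate numbers.
#'
#' @param X an [expression_matrix()] or numeric matrix.
#' @param zero_variance what to do with constant columns: `"drop"` removes
#'   them and records their indices, `"error"` aborts naming the feature.
#' @param sd_method `"sample"` (n-1) or `"population"` (n).
#' @return the normalized matrix with class `"norm_matrix"`; attributes
#'   `dropped_features` (integer indices into the input columns) and
#'   `source_feature_index` (for each retained column, its index in the
#'   input) record the provenance.
#' @export
normalize_columns <- function(X, zero_variance = c("drop", "error"),
                              sd_method = c("sample", "population")) {
  zero_variance <- match.arg(zero_variance)
  sd_method <- match.arg(sd_method)
  X <- as.matrix(X); X <- as_plain_matrix(X)
  check_finite_matrix(X, "matrix to normalize")
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 subjects to normalize", call. = FALSE)
  mu <- colMeans(X)
  ctr <- sweep(X, 2L, mu)
  ss <- colSums(ctr^2)
  denom <- if (sd_method == "sample") n - 1 else n
  sdv <- sqrt(ss / denom)
  const <- sdv <= 0 | ss < .Machine$double.eps * n * pmax(mu^2, 1)
  if (any(const)) {
    ids <- colnames(X)[const]
    if (zero_variance == "error")
      stop("degenerate column(s) with zero variance: ",
           paste(utils::head(ids, 5L), collapse = ", "), call. = FALSE)
  }
  keep <- which(!const)
  W <- sweep(ctr[, keep, drop = FALSE], 2L, sdv[keep], "/")
  class(W) <- c("norm_matrix", class(W))
  attr(W, "dropped_features") <- which(const)
  attr(W, "source_feature_index") <- keep
  W
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("normalized matrix: %d subjects x %d features (%d dropped)\n",
              nrow(x), ncol(x), length(attr(x, "dropped_features"))))
  invisible(x)
}

#' Filter features with few nonzero entries
#'
#' Removes features whose fraction of nonzero entries across subjects is
#' strictly below `min_frac`, the standard low-expression gene filter for
#' single-cell log-count matrices. A feature nonzero in exactly
#' `min_frac * n` subjects is retained (strict-less rule), and all-zero
#' features are removed for any positive threshold.
#'
#' @param X an [expression_matrix()].
#' @param min_frac minimum nonzero fraction in `[0, 1]`; default 0.05.
#' @return the filtered [expression_matrix()].
#' @export
filter_low_nonzero <- function(X, min_frac = 0.05) {
  stopifnot(min_frac >= 0, min_frac <= 1)
  X <- as.matrix(X)
  frac <- colMeans(as_plain_matrix(X) != 0)
  keep <- frac >= min_frac
  if (!any(keep))
    stop("all features removed by the nonzero-fraction filter; ",
         "lower min_frac (currently ", min_frac, ")", call. = FALSE)
  expression_matrix(as_plain_matrix(X)[, keep, drop = FALSE])
}

#' Generate planted-mean clustered data
#'
#' Simulates the K-class planted-mean model: each subject i carries a one-hot
#' membership vector pi_i drawn from `balance`; class k has mean vector
#' mu_k = baseline + gamma_k where the class contrasts gamma_k = mu_k - mu_bar
#' are supported on `n_useful` shared features with entries of magnitude
#' `effect_size`; Gaussian noise with standard deviation `noise_sd` is added.
#' Each support feature receives a signed two-class contrast pattern
#' (+effect_size for one class, -effect_size for a second, 0 otherwise),
#' with the class pairs cycling so that every class is touched; together with
#' the constant baseline this makes mu_1..mu_K linearly independent, so the
#' noiseless signal matrix has rank exactly K (and rank K-1 after column
#' centering).
#'
#' @param n,p number of subjects and features.
#' @param K number of classes (>= 2).
#' @param n_useful number of support features (>= K-1 for full signal rank).
#' @param effect_size magnitude of the nonzero class-mean contrasts.
#' @param noise_sd Gaussian noise standard deviation.
#' @param balance probability vector over the K classes (default uniform).
#' @param seed integer seed; the same seed reproduces the data exactly.
#' @param baseline common mean added to every feature (default 1).
#' @return a list with components `X` (an [expression_matrix()]),
#'   `labels` (integer class labels in 1..K) and `design` (list with the
#'   membership matrix `Pi`, class-mean matrix `M` (p x K), `support`
#'   indices, `noise_sd`, `balance`, `seed`).
#' @export
generate_planted_data <- function(n, p, K, n_useful, effect_size,
                                  noise_sd = 1, balance = NULL, seed = 1L,
                                  baseline = 1) {
  stopifnot(n >= 1, p >= 1, n_useful <= p, K >= 2)
  if (K > n) stop("infeasible design: more classes (", K, ") than subjects (",
                  n, ")", call. = FALSE)
  if (is.null(balance)) balance <- rep(1 / K, K)
  stopifnot(length(balance) == K, all(balance >= 0), sum(balance) > 0)
  if (n_useful < K - 1)
    warning("n_useful < K-1: class means cannot be linearly independent")
  with_seed(seed, {
    labels <- sample.int(K, n, replace = TRUE, prob = balance)
    support <- sort(sample.int(p, n_useful))
    # contrast matrix Gamma: p x K, zero off support
    Gamma <- matrix(0, p, K)
    if (n_useful > 0) {
      cls <- ((seq_len(n_useful) - 1L) %% K) + 1L      # class getting +e
      nxt <- (cls %% K) + 1L                           # class getting -e
      sgn <- sample(c(-1, 1), n_useful, replace = TRUE)
      for (t in seq_len(n_useful)) {
        j <- support[t]
        Gamma[j, cls[t]] <- sgn[t] * effect_size
        Gamma[j, nxt[t]] <- -sgn[t] * effect_size
      }
    }
    M <- baseline + Gamma                              # p x K class means
    Pi <- matrix(0L, n, K)
    Pi[cbind(seq_len(n), labels)] <- 1L
    X <- Pi %*% t(M)                                   # n x p signal = Pi M'
    if (noise_sd > 0)
      X <- X + matrix(stats::rnorm(n * p, sd = noise_sd), n, p)
    X <- expression_matrix(X)
    design <- structure(
      list(K = K, Pi = Pi, M = M, support = support, noise_sd = noise_sd,
           balance = balance, effect_size = effect_size,
           baseline = baseline, seed = seed),
      class = "planted_design")
    list(X = X, labels = labels, design = design)
  })
}

#' @export
print.planted_design <- function(x, ...) {
  cat(sprintf("planted design: K=%d, |support|=%d, effect=%g, noise sd=%g\n",
              x$K, length(x$support), x$effect_size, x$noise_sd))
  invisible(x)
}
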