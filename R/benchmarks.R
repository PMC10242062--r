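#' Published microarray clustering-error benchmark
#'
#' Reported numbers of clustering errors (misclustered subjects under the
#' optimal cluster matching) for eight clustering methods on ten classic
#' gene microarray data sets (Brain, Breast cancer, Colon cancer, Leukemia,
#' two lung cancer cohorts, Lymphoma, Prostate cancer, SRBCT, Su cancer).
#' Bundled as the worked-example input for the rank/regret aggregation in
#' [summarize_table()]; the underlying expression matrices are public but
#' are not shipped with the package.
#'
#' @return integer matrix, data sets x methods.
#' @export
microarray_error_table <- function() {
  m <- rbind(
    "Brain"           = c(14, 6, 11, 7, 14, 17, 21, 21),
    "Breast cancer"   = c(121, 121, 112, 91, 105, 130, 120, 118),
    "Colon cancer"    = c(28, 30, 25, 26, 29, 23, 25, 25),
    "Leukemia"        = c(2, 21, 5, 3, 28, 17, 20, 12),
    "Lung cancer (1)" = c(18, 22, 5, 24, 21, 64, 6, 7),
    "Lung cancer (2)" = c(44, 88, 44, 45, 66, 80, 44, 44),
    "Lymphoma"        = c(1, 14, 1, 18, 23, 22, 16, 10),
    "Prostate cancer" = c(43, 43, 39, 44, 41, 45, 42, 41),
    "SRBCT"           = c(28, 32, 28, 24, 33, 26, 30, 23),
    "Su cancer"       = c(83, 85, 58, 57, 62, 60, 57, 57))
  colnames(m) <- c("k-means", "SpecGem", "IF-PCA", "IF-PCA(X)",
                   "VAE", "VAE(X)", "IF-VAE", "IF-VAE(X)")
  m
}

#' Published single-cell clustering-accuracy benchmark
#'
#' Reported clustering accuracies (correctly clustered cells / total cells)
#' for seven methods on eight single-cell RNA-seq data sets (Camp1, Camp2,
#' Darmanis, Deng, Goolam, Grun, Li, Patel). SC3 is NA on Patel because its
#' gene filter removes every gene there; SC3(NGF) is the same method with
#' the gene filter disabled.
#'
#' @return numeric matrix, data sets x methods, with one NA cell.
#' @export
scrna_accuracy_table <- function() {
  m <- rbind(
    Camp1    = c(0.637, 0.750, 0.627, 0.738, 0.736, 0.660, 0.700),
    Camp2    = c(0.661, 0.713, 0.759, 0.601, 0.656, 0.393, 0.491),
    Darmanis = c(0.682, 0.826, 0.867, 0.635, 0.747, 0.406, 0.617),
    Deng     = c(0.530, 0.590, 0.754, 0.791, 0.588, 0.607, 0.687),
    Goolam   = c(0.621, 0.758, 0.629, 0.637, 0.700, 0.612, 0.703),
    Grun     = c(0.994, 0.509, 0.511, 0.740, 0.657, 0.595, 0.753),
    Li       = c(0.934, 0.938, 0.980, 0.889, 0.968, 0.848, 0.853),
    Patel    = c(0.898, NA, 0.995, 0.795, 0.934, 0.325, 0.465))
  colnames(m) <- c("Seurat", "SC3", "SC3(NGF)", "IF-PCA", "IF-PCA(X)",
                   "IF-VAE", "IF-VAE(X)")
  m
}

#' Published single-cell ARI benchmark
#'
#' Adjusted Rand index companion to [scrna_accuracy_table()] for the same
#' data sets and methods.
#'
#' @return numeric matrix, data sets x methods, with one NA cell.
#' @export
scrna_ari_table <- function() {
  m <- rbind(
    Camp1    = c(0.534, 0.768, 0.526, 0.628, 0.627, 0.606, 0.615),
    Camp2    = c(0.443, 0.577, 0.502, 0.410, 0.493, 0.162, 0.304),
    Darmanis = c(0.480, 0.682, 0.784, 0.489, 0.650, 0.219, 0.525),
    Deng     = c(0.442, 0.646, 0.669, 0.771, 0.477, 0.487, 0.555),
    Goolam   = c(0.543, 0.687, 0.544, 0.356, 0.562, 0.410, 0.534),
    Grun     = c(0.969, -0.066, -0.060, 0.135, 0.102, 0.023, 0.137),
    Li       = c(0.904, 0.951, 0.968, 0.797, 0.940, 0.798, 0.792),
    Patel    = c(0.790, NA, 0.989, 0.598, 0.850, 0.173, 0.235))
  colnames(m) <- c("Seurat", "SC3", "SC3(NGF)", "IF-PCA", "IF-PCA(X)",
                   "IF-VAE", "IF-VAE(X)")
  m
}
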