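#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to the same empirical distribution: the
#' value at rank r in each column becomes the mean across columns of the
#' r-th order statistics, with ties receiving the average of the tied
#' quantiles. Applied on the log2 scale; idempotent. This takes the place
#' of probe-level model-based normalization when the pipeline's entry
#' point is an already-summarized expression matrix.
#'
#' @param em an [expression_matrix()]; at least two samples, no missing
#'   values.
#' @return an [expression_matrix()] with normalized values and identical
#'   labels/metadata.
#' @export
quantile_normalize <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (ncol(em$values) < 2) stop_config("quantile normalization needs >=2 samples")
  if (anyNA(em$values))
    stop_config("expression matrix contains missing values; impute upstream")
  norm <- limma::normalizeQuantiles(em$values, ties = TRUE)
  dimnames(norm) <- dimnames(em$values)
  expression_matrix(norm, em$samples, em$timepoints)
}

#' Principal component analysis of samples
#'
#' Samples are observations, genes are (centered, unscaled) variables.
#' Explained-variance fractions are the eigenvalue shares of the sample
#' covariance matrix, so they are non-negative, non-increasing and sum to
#' at most 1.
#'
#' @param em an [expression_matrix()] with >= 2 samples.
#' @param n_components number of components to return (clamped to the
#'   available rank).
#' @return An object of class `PCAResult`: list with `scores` (samples x
#'   components), `var_explained` (fraction per returned component) and
#'   `sdev` (all singular standard deviations).
#' @export
pca_samples <- function(em, n_components = 2) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (ncol(em$values) < 2) stop_config("PCA needs >=2 samples")
  p <- stats::prcomp(t(em$values), center = TRUE, scale. = FALSE)
  total <- sum(p$sdev^2)
  k <- min(n_components, ncol(p$x))
  structure(list(
    scores = p$x[, seq_len(k), drop = FALSE],
    var_explained = if (total > 0) p$sdev[seq_len(k)]^2 / total else rep(0, k),
    sdev = p$sdev
  ), class = "PCAResult")
}

#' Hierarchical clustering of samples on correlation distance
#'
#' Distance between samples i and j is `1 - Pearson r(i, j)` (range 0 to
#' 2); merging uses complete linkage. This reproduces the standard
#' unsupervised QC view in which replicate arrays merge first and
#' condition/cell-type structure appears in the upper merges.
#'
#' @param em an [expression_matrix()] with >= 2 samples, each with
#'   positive variance across genes.
#' @return An `hclust` object (also class `DendrogramSpec`) whose
#'   `$height` values are complete-linkage correlation distances.
#' @export
hcluster_samples <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (ncol(em$values) < 2) stop_config("clustering needs >=2 samples")
  v <- apply(em$values, 2, stats::var)
  if (any(v == 0))
    stop_config("zero-variance sample(s): %s",
                paste(colnames(em$values)[v == 0], collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(em$values))
  hc <- stats::hclust(d, method = "complete")
  class(hc) <- c("DendrogramSpec", class(hc))
  hc
}
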