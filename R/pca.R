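#' Fit covariance PCA with the cumulative proportion-of-variance rule
#'
#' Centers the data per gene, takes the eigendecomposition of the sample
#' covariance matrix (denominator M-1), and retains the smallest number of
#' leading components whose cumulative proportion of variance reaches
#' `ppv_threshold`. For the microarray regime (genes >> samples) the
#' eigenpairs are obtained through the SVD of the centered data matrix,
#' which is mathematically identical to diagonalizing the covariance:
#' eigenvalues are squared singular values over M-1, loadings are the right
#' singular vectors.
#'
#' Sign convention: the largest-magnitude entry of each loading column is
#' made positive. Ties between equal eigenvalues keep the decomposition's
#' original order (stable).
#'
#' @param X Numeric samples x genes matrix (M >= 2, finite values).
#' @param ppv_threshold Cumulative variance fraction to reach, default 0.95.
#' @return A `pca_model`: list with `gene_means` (length N), `eigenvalues`
#'   (descending, length min(M, N), clipped at 0), `loadings` (N x k),
#'   `k`, `cum_ppv` (cumulative variance fraction at k), `ppv_threshold`.
#' @export
fit_pca <- function(X, ppv_threshold = 0.95) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("PCA requires at least 2 samples")
  if (any(!is.finite(X))) stop("PCA input contains non-finite values")
  M <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu, "-")
  sv <- svd(Xc)
  ev <- sv$d^2 / (M - 1)
  ev[ev < 0] <- 0
  total <- sum(ev)
  if (total <= 0) stop("degenerate data: zero total variance")
  cum <- cumsum(ev) / total
  k <- which(cum >= ppv_threshold)[1]
  if (is.na(k)) k <- length(ev)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  # fix each column's sign so its largest-|entry| is positive
  flip <- vapply(seq_len(k), function(j) {
    v <- loadings[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  loadings <- sweep(loadings, 2, flip, "*")
  structure(
    list(
      gene_means = mu,
      eigenvalues = ev,
      loadings = loadings,
      k = k,
      cum_ppv = cum[k],
      ppv_threshold = ppv_threshold
    ),
    class = "pca_model"
  )
}

#' Proportion of variance per component
#'
#' Each eigenvalue's share of the total variance. Small negative values
#' (within `tol` of zero, numerical noise from the decomposition) are
#' clipped to 0 before normalizing.
#'
#' @param eigenvalues Numeric vector, descending.
#' @param tol Clipping tolerance for negative noise, default 1e-10 relative
#'   to the largest eigenvalue.
#' @return Numeric vector summing to 1.
#' @export
proportion_of_variance <- function(eigenvalues, tol = 1e-10) {
  ev <- eigenvalues
  lim <- -tol * max(1, max(ev, 0))
  if (any(ev < lim)) stop("eigenvalues substantially negative: not a PSD spectrum")
  ev[ev < 0] <- 0
  total <- sum(ev)
  if (total <= 0) stop("degenerate spectrum: all eigenvalues zero")
  ev / total
}

#' Project data onto a fitted PCA basis
#'
#' Subtracts the model's gene means (fitted on calibration data only) and
#' projects onto the retained loadings. This is the leakage-free transform:
#' held-out samples never contribute to the means or covariance.
#'
#' @param model A `pca_model` from [fit_pca()].
#' @param X Samples x genes matrix over the model's genes.
#' @return Scores matrix, samples x k.
#' @export
pca_transform <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$gene_means)) {
    stop(sprintf("model fitted on %d genes, data has %d columns",
                 length(model$gene_means), ncol(X)))
  }
  sweep(X, 2, model$gene_means, "-") %*% model$loadings
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d genes, %d retained components (cum. PPV %.3f >= %.2f)\n",
              length(x$gene_means), x$k, x$cum_ppv, x$ppv_threshold))
  invisible(x)
}
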