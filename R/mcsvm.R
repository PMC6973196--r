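#' Train a multiclass soft-margin SVM on a precomputed Gram matrix
#'
#' Solves the soft-margin problem in its dual form on a precomputed kernel
#' matrix, decomposing the multiclass task one-vs-one: one binary machine
#' per unordered class pair, each trained only on that pair's rows/columns
#' of the Gram matrix, with majority voting at prediction. The quadratic
#' programs are solved by kernlab's C-svc SMO; ties in the vote go to the
#' lowest class index (the solver scans classes in order).
#'
#' An indefinite Gram matrix (a hybrid-kernel parameter set that fails the
#' Mercer check) is accepted with a warning carrying its smallest
#' eigenvalue, since the SMO solver tolerates mildly indefinite kernels;
#' see `strict_psd` in the pipeline to upgrade this to an error.
#'
#' @param K_train n x n symmetric Gram matrix over the training samples.
#' @param labels Integer class codes (0-based), length n, >= 2 classes.
#' @param C Penalty for margin violations, > 0.
#' @param warn_indefinite Check the spectrum and warn when K is not PSD
#'   (default TRUE).
#' @return An `mcsvm_model`: list with the fitted solver object (`fit`),
#'   `classes` (integer codes in solver order), `C`, `n_train`, and
#'   `psd` (the [check_psd()] result, or NULL when not checked).
#' @export
train_mcsvm <- function(K_train, labels, C, warn_indefinite = TRUE) {
  K_train <- as.matrix(K_train)
  if (anyNA(K_train) || any(!is.finite(K_train))) stop("Gram matrix contains non-finite values")
  if (nrow(K_train) != ncol(K_train)) stop("K_train must be square")
  if (nrow(K_train) != length(labels)) {
    stop(sprintf("%d labels for a %d x %d Gram matrix",
                 length(labels), nrow(K_train), ncol(K_train)))
  }
  if (C <= 0) stop("C must be > 0")
  y <- factor(labels)
  if (nlevels(y) < 2) stop("training data contains a single class")
  psd <- NULL
  if (warn_indefinite) {
    psd <- check_psd(K_train, tol = 1e-8)
    if (!psd$is_psd) {
      warning(sprintf(
        "Gram matrix is not positive semidefinite (min eigenvalue %.4g); training anyway",
        psd$min_eigenvalue
      ))
    }
  }
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K_train), y,
                       type = "C-svc", C = C)
  structure(
    list(
      fit = fit,
      classes = as.integer(levels(y)),
      C = C,
      n_train = nrow(K_train),
      psd = psd
    ),
    class = "mcsvm_model"
  )
}

#' Predict classes from a cross Gram matrix
#'
#' @param model An `mcsvm_model`.
#' @param K_test_train m x n matrix of kernel values between the m test
#'   samples (rows) and the n training samples (columns, in training order).
#' @return Integer vector of predicted class codes (0-based), length m.
#' @export
predict_mcsvm <- function(model, K_test_train) {
  K_test_train <- as.matrix(K_test_train)
  if (ncol(K_test_train) != model$n_train) {
    stop(sprintf("cross Gram has %d columns, model was trained on %d samples",
                 ncol(K_test_train), model$n_train))
  }
  sv <- kernlab::SVindex(model$fit)
  pred <- kernlab::predict(
    model$fit,
    kernlab::as.kernelMatrix(K_test_train[, sv, drop = FALSE])
  )
  as.integer(as.character(pred))
}

#' Dual-solution diagnostics for every pairwise machine
#'
#' Extracts, for each one-vs-one binary machine, the violation of its dual
#' constraints: the box constraint `0 <= alpha_i <= C` and the equality
#' constraint `sum alpha_i y_i = 0`.
#'
#' @param model An `mcsvm_model`.
#' @return Data frame with one row per class pair: `max_alpha`,
#'   `box_violation` (amount by which any alpha leaves `[0, C]`), and
#'   `abs_coef_sum` (`|sum alpha_i y_i|`).
#' @export
mcsvm_dual_diagnostics <- function(model) {
  a <- kernlab::alpha(model$fit)
  co <- kernlab::coef(model$fit)
  n_pairs <- length(a)
  data.frame(
    pair = seq_len(n_pairs),
    max_alpha = vapply(a, function(v) if (length(v)) max(v) else 0, numeric(1)),
    box_violation = vapply(a, function(v) {
      if (!length(v)) return(0)
      max(0, max(v) - model$C, -min(v))
    }, numeric(1)),
    abs_coef_sum = vapply(co, function(v) abs(sum(v)), numeric(1))
  )
}

#' @export
print.mcsvm_model <- function(x, ...) {
  C_cls <- length(x$classes)
  cat(sprintf(
    "mcsvm_model: %d classes (%d pairwise machines), C = %.4g, %d training samples\n",
    C_cls, C_cls * (C_cls - 1) / 2, x$C, x$n_train
  ))
  invisible(x)
}
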