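#' Kernel parameter set
#'
#' Bundles the parameters of the four supported kernels. The hybrid
#' linear-Gaussian-polynomial (LGP) kernel mixes a linear term with a
#' Gaussian-type envelope of the polynomial kernel:
#'
#'   K(x, y) = beta1 * (x.y) + beta2 * exp(-beta3 * (eta*(x.y) + delta)^d / (2 sigma^2))
#'
#' with mixing weights on the simplex (beta1 + beta2 + beta3 = 1, each in
#' \[0, 1\]). The Gaussian width may be given either as `sigma` or as
#' `gamma = 1 / (2 sigma^2)`.
#'
#' @param kind One of `"linear"`, `"polynomial"`, `"gaussian"`, `"lgp"`.
#' @param beta Length-3 mixing weights (lgp only).
#' @param eta Polynomial slope, > 0 (polynomial, lgp).
#' @param delta Polynomial offset, >= 0 (polynomial, lgp).
#' @param degree Polynomial degree, integer >= 1 (polynomial, lgp; the
#'   search space restricts it to 2..5).
#' @param sigma Gaussian width, > 0 (gaussian, lgp).
#' @param gamma Alternative to `sigma`: `gamma = 1/(2 sigma^2)`.
#' @return A `kernel_params` object.
#' @export
kernel_params <- function(kind = c("linear", "polynomial", "gaussian", "lgp"),
                          beta = NULL, eta = NULL, delta = NULL,
                          degree = NULL, sigma = NULL, gamma = NULL) {
  kind <- match.arg(kind)
  if (!is.null(gamma)) {
    if (!is.null(sigma)) stop("supply sigma or gamma, not both")
    if (gamma <= 0) stop("gamma must be > 0")
    sigma <- 1 / sqrt(2 * gamma)
  }
  need_poly <- kind %in% c("polynomial", "lgp")
  need_gauss <- kind %in% c("gaussian", "lgp")
  if (need_poly) {
    if (is.null(eta) || eta <= 0) stop("eta must be supplied and > 0")
    if (is.null(delta) || delta < 0) stop("delta must be supplied and >= 0")
    if (is.null(degree) || degree < 1 || degree != round(degree)) {
      stop("degree must be a positive integer")
    }
    degree <- as.integer(degree)
  }
  if (need_gauss) {
    if (is.null(sigma) || sigma <= 0) stop("sigma must be supplied and > 0")
  }
  if (kind == "lgp") {
    if (is.null(beta) || length(beta) != 3) stop("beta must be a length-3 vector")
    if (any(beta < 0) || any(beta > 1) || abs(sum(beta) - 1) > 1e-9) {
      stop("beta must lie on the simplex: each in [0,1], summing to 1")
    }
  }
  structure(
    list(kind = kind, beta = beta, eta = eta, delta = delta,
         degree = degree, sigma = sigma),
    class = "kernel_params"
  )
}

#' @export
print.kernel_params <- function(x, ...) {
  fmt <- switch(x$kind,
    linear = "kernel_params: linear",
    polynomial = sprintf("kernel_params: polynomial (eta=%.4g, delta=%.4g, d=%d)",
                         x$eta, x$delta, x$degree),
    gaussian = sprintf("kernel_params: gaussian (sigma=%.4g)", x$sigma),
    lgp = sprintf(
      "kernel_params: lgp (beta=%.3f/%.3f/%.3f, eta=%.4g, delta=%.4g, d=%d, sigma=%.4g)",
      x$beta[1], x$beta[2], x$beta[3], x$eta, x$delta, x$degree, x$sigma
    )
  )
  cat(fmt, "\n")
  invisible(x)
}

check_lengths <- function(x, y) {
  if (length(x) != length(y)) {
    stop(sprintf("vector length mismatch: %d vs %d", length(x), length(y)))
  }
}

#' Linear kernel
#' @param x,y Numeric vectors of equal length.
#' @return The dot product `x . y`.
#' @export
linear_kernel <- function(x, y) {
  check_lengths(x, y)
  sum(x * y)
}

#' Polynomial kernel
#' @param x,y Numeric vectors of equal length.
#' @param eta Slope, > 0.
#' @param delta Offset.
#' @param degree Positive integer degree.
#' @return `(eta * (x . y) + delta)^degree`.
#' @export
polynomial_kernel <- function(x, y, eta, delta, degree) {
  check_lengths(x, y)
  if (eta <= 0) stop("eta must be > 0")
  if (degree < 1 || degree != round(degree)) stop("degree must be a positive integer")
  (eta * sum(x * y) + delta)^degree
}

#' Gaussian (RBF) kernel
#' @param x,y Numeric vectors of equal length.
#' @param sigma Width, > 0.
#' @return `exp(-||x - y||^2 / (2 sigma^2))`, in (0, 1].
#' @export
gaussian_kernel <- function(x, y, sigma) {
  check_lengths(x, y)
  if (sigma <= 0) stop("sigma must be > 0")
  exp(-sum((x - y)^2) / (2 * sigma^2))
}

#' Hybrid linear-Gaussian-polynomial (LGP) kernel
#'
#' A convex blend of global and local similarity: the linear term preserves
#' large-scale structure while the Gaussian envelope of the polynomial
#' kernel contributes a bounded, locally adaptive term. With
#' `beta = (1, 0, 0)` it reduces exactly to the linear kernel; with
#' `beta3 = 0` the exponential term is constant 1.
#'
#' @param x,y Numeric vectors of equal length.
#' @param params A `kernel_params` of kind `"lgp"`.
#' @return Kernel value.
#' @export
lgp_kernel <- function(x, y, params) {
  check_lengths(x, y)
  if (params$kind != "lgp") stop("params must have kind 'lgp'")
  dot <- sum(x * y)
  kpoly <- (params$eta * dot + params$delta)^params$degree
  params$beta[1] * dot +
    params$beta[2] * exp(-params$beta[3] * kpoly / (2 * params$sigma^2))
}

#' Truncated-series oracle for the LGP kernel
#'
#' Expands the exponential term of the LGP kernel as a Taylor series in the
#' polynomial kernel:
#'
#'   beta1 * K_lin + beta2 * sum_{i=0}^{n} (-beta3 * gamma)^i * K_poly^i / i!
#'
#' with `gamma = 1/(2 sigma^2)`. This exposes the hybrid kernel's structure
#' as a weighted linear kernel plus a signed series of polynomial kernels,
#' and serves as an independent numerical check of the closed form.
#'
#' The truncation is only meaningful inside its convergence region: the
#' remainder after `n_terms` terms is bounded by the first omitted term,
#' `|beta3 * gamma * K_poly|^(n+1) / (n+1)!` (see [lgp_series_bound()]).
#' For large exponent arguments the partial sums are dominated by
#' floating-point cancellation and the oracle is uninformative.
#'
#' @param x,y Numeric vectors of equal length.
#' @param params A `kernel_params` of kind `"lgp"`.
#' @param n_terms Truncation order `n >= 0` (number of series terms beyond
#'   the zeroth is `n_terms`).
#' @return Truncated series value.
#' @export
lgp_series_oracle <- function(x, y, params, n_terms) {
  check_lengths(x, y)
  if (n_terms < 0) stop("n_terms must be >= 0")
  dot <- sum(x * y)
  kpoly <- (params$eta * dot + params$delta)^params$degree
  z <- -params$beta[3] * kpoly / (2 * params$sigma^2)
  # cumulative-product evaluation of sum z^i / i!
  term <- 1
  acc <- 1
  if (n_terms >= 1) {
    for (i in seq_len(n_terms)) {
      term <- term * z / i
      acc <- acc + term
    }
  }
  params$beta[1] * dot + params$beta[2] * acc
}

#' Remainder bound for the truncated LGP series
#'
#' First-omitted-term bound on the truncation error of
#' [lgp_series_oracle()]: `|z|^(n+1) / (n+1)!` with
#' `z = beta3 * K_poly / (2 sigma^2)`, valid once the terms are decreasing
#' (`|z| < n + 2`); outside that region the series has not yet converged and
#' the bound reported is `Inf`.
#'
#' @inheritParams lgp_series_oracle
#' @return Non-negative error bound (possibly `Inf`).
#' @export
lgp_series_bound <- function(x, y, params, n_terms) {
  dot <- sum(x * y)
  kpoly <- (params$eta * dot + params$delta)^params$degree
  z <- abs(params$beta[3] * kpoly / (2 * params$sigma^2))
  if (z >= n_terms + 2) return(Inf)
  params$beta[2] * exp((n_terms + 1) * log(z + .Machine$double.xmin) -
                         lfactorial(n_terms + 1))
}

#' Gram (kernel) matrix between two sample sets
#'
#' Computes all pairwise kernel values between the rows of `A` and `B`,
#' vectorized over the cross-product matrix. `gram_matrix(A, A, params)`
#' is symmetric (enforced exactly by averaging with its transpose).
#'
#' @param A m x p numeric matrix.
#' @param B n x p numeric matrix; defaults to `A`.
#' @param params A `kernel_params`.
#' @return m x n matrix of kernel values.
#' @export
gram_matrix <- function(A, B = NULL, params) {
  A <- as.matrix(A)
  same <- is.null(B)
  B <- if (same) A else as.matrix(B)
  if (ncol(A) != ncol(B)) {
    stop(sprintf("feature dimension mismatch: %d vs %d", ncol(A), ncol(B)))
  }
  dots <- tcrossprod(A, B)
  K <- switch(params$kind,
    linear = dots,
    polynomial = (params$eta * dots + params$delta)^params$degree,
    gaussian = {
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * dots
      d2[d2 < 0] <- 0
      exp(-d2 / (2 * params$sigma^2))
    },
    lgp = {
      kpoly <- (params$eta * dots + params$delta)^params$degree
      params$beta[1] * dots +
        params$beta[2] * exp(-params$beta[3] * kpoly / (2 * params$sigma^2))
    },
    stop("unknown kernel kind")
  )
  if (same) K <- (K + t(K)) / 2
  K
}

#' Boundedness of the hybrid kernel over a sample set
#'
#' The exponential term of the LGP kernel is a Gaussian-type envelope and
#' is only meaningful while its exponent stays non-positive, i.e. while
#' the polynomial base `eta * (x.y) + delta` is non-negative or the degree
#' is even. With an odd degree and sufficiently negative dot products
#' (routine on centered PCA scores) the term explodes toward overflow.
#' This predicate reports whether a parameter set keeps the envelope
#' bounded in (0, 1] over all row pairs of `A` and `B` — the pipeline's
#' feasibility gate for swarm candidates.
#'
#' @param A m x p numeric matrix.
#' @param B n x p matrix; defaults to `A`.
#' @param params A `kernel_params`.
#' @return TRUE when every pairwise kernel value is bounded.
#' @export
kernel_bounded <- function(A, B = NULL, params) {
  if (params$kind != "lgp") return(TRUE)
  if (params$beta[2] == 0 || params$beta[3] == 0) return(TRUE)
  if (params$degree %% 2 == 0) return(TRUE)
  A <- as.matrix(A)
  B <- if (is.null(B)) A else as.matrix(B)
  params$eta * min(tcrossprod(A, B)) + params$delta >= 0
}

#' Numerical positive-semidefiniteness check
#'
#' Mercer's condition in matrix form: a kernel is admissible only if every
#' Gram matrix it produces is symmetric PSD. This checks the spectrum of a
#' given matrix, declaring it PSD when the smallest eigenvalue is no less
#' than `-tol * max(1, largest eigenvalue)`.
#'
#' @param K Square symmetric matrix.
#' @param tol Relative tolerance, default 1e-8.
#' @return List with `is_psd` (logical) and `min_eigenvalue`.
#' @export
check_psd <- function(K, tol = 1e-8) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("K must be square")
  asym <- max(abs(K - t(K)))
  if (asym > tol * max(1, max(abs(K)))) {
    stop(sprintf("matrix is asymmetric beyond tolerance (max |K - K'| = %.3g)", asym))
  }
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  list(
    is_psd = min(ev) >= -tol * max(1, max(ev)),
    min_eigenvalue = min(ev)
  )
}
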