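test_that("scalar kernels reproduce hand-computed values", {
  expect_equal(linear_kernel(c(1, 2), c(3, 4)), 11)
  expect_equal(linear_kernel(c(0, 0), c(0, 0)), 0)
  x <- c(0.3, -0.7, 0.2)
  expect_equal(linear_kernel(x, x), sum(x^2))
  expect_error(linear_kernel(c(1, 2), c(1, 2, 3)), "mismatch")

  expect_equal(polynomial_kernel(c(1, 2), c(3, 4), eta = 1, delta = 1, degree = 2), 144)
  expect_equal(polynomial_kernel(c(1, 0), c(0, 1), eta = 2, delta = 0, degree = 3), 0)
  # degree 1 reduces to eta * linear + delta
  expect_equal(polynomial_kernel(x, 2 * x, eta = 0.5, delta = 1.5, degree = 1),
               0.5 * linear_kernel(x, 2 * x) + 1.5)
  expect_error(polynomial_kernel(c(1), c(1), eta = 1, delta = 0, degree = 0), "degree")

  expect_equal(gaussian_kernel(x, x, sigma = 2), 1)
  expect_equal(gaussian_kernel(c(1, 0), c(0, 1), sigma = 1), exp(-1))
  d <- seq(0, 3, by = 0.5)
  vals <- vapply(d, function(t) gaussian_kernel(c(0), c(t), sigma = 1), numeric(1))
  expect_true(all(diff(vals) < 0))  # monotone decreasing in distance
  expect_error(gaussian_kernel(x, x, sigma = 0), "sigma")
})

test_that("lgp kernel matches its closed form and reductions", {
  p <- kernel_params("lgp", beta = c(0.5, 0.3, 0.2), eta = 1, delta = 0,
                     degree = 2, sigma = 1)
  expect_equal(lgp_kernel(c(1, 0), c(1, 0), p), 0.5 + 0.3 * exp(-0.1),
               tolerance = 1e-12)

  p_lin <- kernel_params("lgp", beta = c(1, 0, 0), eta = 2, delta = 1,
                         degree = 3, sigma = 0.5)
  withr::with_seed(21, {
    for (i in 1:10) {
      x <- rnorm(4); y <- rnorm(4)
      expect_equal(lgp_kernel(x, y, p_lin), linear_kernel(x, y), tolerance = 1e-12)
    }
  })
  # beta = (0, 1, 0): exponent vanishes, kernel constant 1
  p_const <- kernel_params("lgp", beta = c(0, 1, 0), eta = 1, delta = 2,
                           degree = 2, sigma = 1)
  expect_equal(lgp_kernel(c(3, -2), c(0.5, 4), p_const), 1)

  expect_error(kernel_params("lgp", beta = c(0.5, 0.2, 0.2), eta = 1, delta = 0,
                             degree = 2, sigma = 1), "simplex")
  expect_equal(kernel_params("lgp", beta = c(0.2, 0.3, 0.5), eta = 1, delta = 0,
                             degree = 2, gamma = 0.5)$sigma, 1)
})

test_that("truncated series oracle converges to the closed form", {
  p <- kernel_params("lgp", beta = c(0.5, 0.3, 0.2), eta = 1, delta = 0,
                     degree = 2, sigma = 1)
  x <- c(1, 0); y <- c(1, 0)
  # zeroth order: beta1 * (x.y) + beta2
  expect_equal(lgp_series_oracle(x, y, p, 0), 0.5 + 0.3)
  expect_equal(lgp_series_oracle(x, y, p, 30), lgp_kernel(x, y, p),
               tolerance = 1e-10)
  # truncation error shrinks monotonically once terms decrease
  errs <- vapply(1:12, function(n) {
    abs(lgp_series_oracle(x, y, p, n) - lgp_kernel(x, y, p))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-15))
  # remainder bound dominates the observed error
  expect_lte(errs[5], lgp_series_bound(x, y, p, 5))
})

test_that("gram_matrix agrees with the pairwise loop oracle for all kinds", {
  withr::with_seed(77, {
    A <- matrix(rnorm(18), 6, 3)
    B <- matrix(rnorm(12), 4, 3)
    kinds <- list(
      kernel_params("linear"),
      kernel_params("polynomial", eta = 0.7, delta = 1.2, degree = 3),
      kernel_params("gaussian", sigma = 1.4),
      kernel_params("lgp", beta = c(0.4, 0.35, 0.25), eta = 0.5, delta = 0.3,
                    degree = 2, sigma = 1.1)
    )
    for (p in kinds) {
      expect_equal(gram_matrix(A, B, p), gram_loop(A, B, p), tolerance = 1e-10)
      K <- gram_matrix(A, params = p)
      expect_equal(K, t(K))
      expect_equal(K, gram_loop(A, A, p), tolerance = 1e-10)
    }
  })
  expect_equal(gram_matrix(diag(3), params = kernel_params("linear")), diag(3))
  expect_error(gram_matrix(matrix(0, 2, 3), matrix(0, 2, 4), kernel_params("linear")),
               "dimension")
})

test_that("check_psd classifies spectra correctly", {
  r <- check_psd(diag(2))
  expect_true(r$is_psd)
  expect_equal(r$min_eigenvalue, 1)
  r2 <- check_psd(rbind(c(1, 2), c(2, 1)))  # eigenvalues 3 and -1
  expect_false(r2$is_psd)
  expect_equal(r2$min_eigenvalue, -1, tolerance = 1e-12)
  expect_error(check_psd(rbind(c(1, 2), c(0, 1))), "asymmetric")
  withr::with_seed(5, {
    X <- matrix(rnorm(40), 8, 5)
  })
  expect_true(check_psd(gram_matrix(X, params = kernel_params("linear")))$is_psd)
})

test_that("convex mixtures of PSD component Grams stay PSD", {
  withr::with_seed(13, {
    for (i in 1:20) {
      X <- matrix(rnorm(8 * 4), 8, 4)
      K_lin <- gram_matrix(X, params = kernel_params("linear"))
      K_gauss <- gram_matrix(X, params = kernel_params("gaussian", sigma = 1))
      b <- random_simplex()
      K_mix <- b[1] * K_lin + (b[2] + b[3]) * K_gauss
      expect_true(check_psd(K_mix)$is_psd)
    }
  })
})

test_that("lgp with beta = (1,0,0) and the linear kernel give identical Grams", {
  withr::with_seed(55, {
    X <- matrix(rnorm(24), 8, 3)
  })
  p <- kernel_params("lgp", beta = c(1, 0, 0), eta = 1, delta = 1, degree = 2, sigma = 1)
  expect_equal(gram_matrix(X, params = p),
               gram_matrix(X, params = kernel_params("linear")),
               tolerance = 1e-12)
})
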