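test_that("separable two-class problem is fit without training errors", {
  X <- rbind(c(0, 0), c(0, 1), c(4, 0), c(4, 1))
  y <- c(0L, 0L, 1L, 1L)
  K <- gram_matrix(X, params = kernel_params("linear"))
  m <- train_mcsvm(K, y, C = 1)
  expect_s3_class(m, "mcsvm_model")
  expect_equal(predict_mcsvm(m, K), y)
  # agreement with an independent solver on the same data
  skip_if_not_installed("e1071")
  ref <- e1071::svm(X, factor(y), kernel = "linear", cost = 1, scale = FALSE)
  expect_equal(predict_mcsvm(m, K),
               as.integer(as.character(predict(ref, X))))
})

test_that("one-vs-one decomposition builds C(C-1)/2 machines", {
  cloud <- separable_cloud(
    n_per_class = 4,
    centers = lapply(0:6, function(i) c(5 * i, 5 * (i %% 2)))
  )
  K <- gram_matrix(cloud$X, params = kernel_params("linear"))
  m <- train_mcsvm(K, cloud$y, C = 1)
  expect_length(kernlab::alpha(m$fit), 21)  # 7 classes
  expect_equal(predict_mcsvm(m, K), cloud$y)
})

test_that("training is deterministic and respects the dual constraints", {
  cloud <- separable_cloud(n_per_class = 6, sd = 1.2)
  K <- gram_matrix(cloud$X, params = kernel_params("gaussian", sigma = 2))
  m1 <- train_mcsvm(K, cloud$y, C = 2)
  m2 <- train_mcsvm(K, cloud$y, C = 2)
  expect_identical(predict_mcsvm(m1, K), predict_mcsvm(m2, K))
  diag1 <- mcsvm_dual_diagnostics(m1)
  expect_equal(nrow(diag1), 3)
  expect_true(all(diag1$box_violation <= 1e-8))
  expect_true(all(diag1$abs_coef_sum <= 1e-6))
  expect_true(all(diag1$max_alpha <= 2 + 1e-8))
})

test_that("gaussian model assigns perturbed prototypes to the nearest class", {
  X <- rbind(c(0, 0), c(10, 0), c(0, 10))
  y <- 0:2
  p <- kernel_params("gaussian", sigma = 1)
  K <- gram_matrix(X, params = p)
  m <- train_mcsvm(K, y, C = 10)
  probes <- X + 0.5
  Kx <- gram_matrix(probes, X, params = p)
  pred <- predict_mcsvm(m, Kx)
  # brute-force nearest-prototype oracle
  nearest <- apply(probes, 1, function(q) {
    which.min(colSums((t(X) - q)^2)) - 1L
  })
  expect_equal(pred, unname(nearest))
})

test_that("precomputed-Gram decisions match the direct-kernel formulation", {
  cloud <- separable_cloud(n_per_class = 5, sd = 1.0, seed = 9)
  sigma <- 1.5
  K <- gram_matrix(cloud$X, params = kernel_params("gaussian", sigma = sigma))
  m_pre <- train_mcsvm(K, cloud$y, C = 1)
  # same solver fed raw features with its own rbf kernel (rbfdot uses
  # exp(-sigma_k * |x-y|^2), so sigma_k = 1/(2 sigma^2))
  m_dir <- kernlab::ksvm(cloud$X, factor(cloud$y), type = "C-svc", C = 1,
                         kernel = "rbfdot",
                         kpar = list(sigma = 1 / (2 * sigma^2)), scaled = FALSE)
  withr::with_seed(3, {
    probes <- cloud$X + matrix(rnorm(length(cloud$X), sd = 0.1), nrow(cloud$X))
  })
  Kx <- gram_matrix(probes, cloud$X, params = kernel_params("gaussian", sigma = sigma))
  expect_equal(predict_mcsvm(m_pre, Kx),
               as.integer(as.character(predict(m_dir, probes))))
})

test_that("invalid training inputs are rejected", {
  K <- diag(3)
  expect_error(train_mcsvm(K, c(0L, 0L, 0L), C = 1), "single class")
  expect_error(train_mcsvm(K, c(0L, 1L), C = 1), "labels")
  Kbad <- K; Kbad[1, 1] <- NaN
  expect_error(train_mcsvm(Kbad, c(0L, 1L, 0L), C = 1), "non-finite")
  expect_error(train_mcsvm(K, c(0L, 1L, 0L), C = -1), "C must be")
  m <- train_mcsvm(gram_matrix(rbind(c(0, 0), c(1, 1)),
                               params = kernel_params("linear")),
                   c(0L, 1L), C = 1, warn_indefinite = FALSE)
  expect_error(predict_mcsvm(m, matrix(0, 2, 5)), "columns")
})

test_that("an indefinite Gram matrix triggers the warning path", {
  p_bad <- kernel_params("lgp", beta = c(0.05, 0.5, 0.45), eta = 1, delta = 0,
                         degree = 2, sigma = 0.25)
  X <- diag(2)
  K <- gram_matrix(X, params = p_bad)
  chk <- check_psd(K)
  expect_false(chk$is_psd)
  expect_lt(chk$min_eigenvalue, 0)
  expect_warning(train_mcsvm(K, c(0L, 1L), C = 1), "not positive semidefinite")
})
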