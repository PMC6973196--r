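# shared fixture builders; everything is generated in code

# brute-force pairwise kernel loop, the oracle gram_matrix is checked against
gram_loop <- function(A, B, params) {
  k_fun <- switch(params$kind,
    linear = function(x, y) linear_kernel(x, y),
    polynomial = function(x, y) {
      polynomial_kernel(x, y, params$eta, params$delta, params$degree)
    },
    gaussian = function(x, y) gaussian_kernel(x, y, params$sigma),
    lgp = function(x, y) lgp_kernel(x, y, params)
  )
  out <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) out[i, j] <- k_fun(A[i, ], B[j, ])
  }
  out
}

# uniform draw from the probability simplex
random_simplex <- function() {
  b <- -log(runif(3))
  b / sum(b)
}

# random lgp parameter set inside the search ranges
random_lgp_params <- function() {
  kernel_params("lgp",
    beta = random_simplex(),
    gamma = 2^runif(1, -15, 3),
    eta = 2^runif(1, -15, 3),
    delta = runif(1, 0, 5),
    degree = sample(2:5, 1)
  )
}

# point uniform in the unit ball of dimension p
unit_ball_point <- function(p) {
  v <- rnorm(p)
  v / sqrt(sum(v^2)) * runif(1)^(1 / p)
}

# small csv fixture written to a temp file; returns its path
write_csv_fixture <- function(genes_in_rows = FALSE) {
  vals <- matrix(c(1.5, 2.5, 3.5, 4.5, 5.5, 6.5), nrow = 3,
                 dimnames = list(paste0("s", 1:3), c("gA", "gB")))
  path <- tempfile(fileext = ".csv")
  if (genes_in_rows) {
    df <- data.frame(gene = colnames(vals), t(vals), check.names = FALSE)
  } else {
    df <- data.frame(sample = rownames(vals), vals,
                     class = c("tumor", "normal", "tumor"), check.names = FALSE)
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# well-separated multiclass point cloud in 2-D
separable_cloud <- function(n_per_class = 8, centers = list(c(0, 0), c(6, 0), c(0, 6)),
                            sd = 0.3, seed = 42) {
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(centers, function(ct) {
      cbind(rnorm(n_per_class, ct[1], sd), rnorm(n_per_class, ct[2], sd))
    }))
    list(X = X, y = rep(seq_along(centers) - 1L, each = n_per_class))
  })
}
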