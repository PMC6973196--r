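test_that("csv round-trip yields the canonical samples x genes layout", {
  path <- write_csv_fixture()
  em <- read_expression_table(path, label_column = "class")
  expect_s3_class(em, "expression_matrix")
  expect_equal(dim(em), c(3L, 2L))
  expect_equal(em$gene_ids, c("gA", "gB"))
  expect_equal(em$labels, c(0L, 1L, 0L))  # first-seen order: tumor = 0
  expect_equal(em$class_names, c("tumor", "normal"))
  expect_equal(unname(em$values[, "gA"]), c(1.5, 2.5, 3.5))
})

test_that("genes-in-rows orientation produces the identical matrix", {
  p1 <- write_csv_fixture()
  p2 <- write_csv_fixture(genes_in_rows = TRUE)
  lab <- tempfile(fileext = ".csv")
  writeLines(c("label", "tumor", "normal", "tumor"), lab)
  em1 <- read_expression_table(p1, label_column = "class")
  em2 <- read_expression_table(p2, orientation = "genes_in_rows", label_file = lab)
  expect_equal(em2$values, em1$values)
  expect_equal(em2$labels, em1$labels)
})

test_that("loader rejects malformed files with located errors", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("sample,gA,gB,class", "s1,1.0,NA,tumor", "s2,2.0,3.0,normal"), path)
  expect_error(read_expression_table(path, label_column = "class"),
               "row 's1', column 'gB'")

  path2 <- tempfile(fileext = ".csv")
  writeLines(c("sample,gA,class", "s1,1.0,tumor", "s1,2.0,normal"), path2)
  expect_error(read_expression_table(path2, label_column = "class"), "duplicate")

  path3 <- tempfile(fileext = ".csv")
  writeLines(c("sample,gA,class", "s1,1.0,tumor", "s2,2.0,"), path3)
  expect_error(read_expression_table(path3, label_column = "class"), "label")
})

test_that("writer output is re-readable", {
  em <- generate_dataset(synth_spec(c(4, 3), n_genes = 5, n_informative = 2,
                                    effect_size = 2, seed = 3))
  path <- tempfile(fileext = ".tsv")
  lab <- tempfile(fileext = ".tsv")
  write_expression_table(em, path, lab)
  back <- read_expression_table(path, label_file = lab)
  expect_equal(back$values, em$values, tolerance = 1e-12)
  expect_equal(back$labels, em$labels)
})

test_that("min-max normalization maps each gene onto [0, 1]", {
  em <- expression_matrix(cbind(g1 = c(2, 4, 10), g2 = c(7, 7, 7)), c(0, 1, 0),
                          class_names = c("a", "b"))
  out <- minmax_normalize(em)
  expect_equal(unname(out$data$values[, 1]), c(0, 0.25, 1))
  expect_equal(unname(out$data$values[, 2]), c(0, 0, 0))  # constant gene -> 0
  expect_equal(unname(out$stats$min), c(2, 7))
  expect_equal(unname(out$stats$max), c(10, 7))
})

test_that("train-fitted stats clip out-of-range test values", {
  train <- expression_matrix(cbind(g = c(0, 10)), c(0, 1), class_names = c("a", "b"))
  fit <- minmax_normalize(train, mode = "train_fitted")
  test <- expression_matrix(cbind(g = c(12, -3, 5)), c(0, 1, 0),
                            class_names = c("a", "b"))
  out <- minmax_normalize(test, stats = fit$stats)
  expect_equal(unname(out$data$values[, 1]), c(1, 0, 0.5))
})

test_that("normalization is idempotent and rank-preserving", {
  withr::with_seed(11, {
    X <- matrix(runif(60, 5, 50), 10, 6)
  })
  em <- expression_matrix(X, rep(0:1, 5), class_names = c("a", "b"))
  once <- minmax_normalize(em)$data
  twice <- minmax_normalize(once)$data
  expect_equal(twice$values, once$values, tolerance = 1e-12)
  for (j in seq_len(ncol(X))) {
    expect_equal(order(once$values[, j]), order(X[, j]))
  }
})

test_that("train/test split is exact, stratified, and reproducible", {
  labels <- rep(c(0L, 1L), c(47, 25))  # the 72-sample two-class benchmark shape
  s1 <- split_train_test(labels, 17, seed = 5)
  expect_length(s1$train_indices, 55)
  expect_length(s1$test_indices, 17)
  expect_setequal(c(s1$train_indices, s1$test_indices), 1:72)
  # largest-remainder quotas: 17 * 47/72 = 11.10, 17 * 25/72 = 5.90 -> 11 + 6
  expect_equal(sum(labels[s1$test_indices] == 0), 11)
  expect_equal(sum(labels[s1$test_indices] == 1), 6)
  s2 <- split_train_test(labels, 17, seed = 5)
  expect_identical(s1, s2)
  s3 <- split_train_test(labels, 0, seed = 5)
  expect_length(s3$train_indices, 72)
  expect_length(s3$test_indices, 0)
})

test_that("stratified split refuses to consume a singleton class", {
  labels <- c(rep(0L, 3), 1L)
  expect_error(split_train_test(labels, 3, seed = 1), "entire class")
  expect_error(split_train_test(labels, 4, seed = 1), "n_test")
})

test_that("fold plan partitions the training set with near-equal folds", {
  labels <- rep(c(0L, 1L), c(40, 32))
  split <- split_train_test(labels, 17, seed = 2)
  fp <- make_fold_plan(split$train_indices, 5, labels, seed = 3)
  expect_length(fp$folds, 5)
  expect_equal(sort(unlist(fp$folds)), sort(split$train_indices))
  sizes <- lengths(fp$folds)
  expect_equal(sum(sizes), 55)
  expect_equal(sizes, rep(11L, 5), ignore_attr = TRUE)
  # stratification: per-fold class counts differ by <= 1 across folds
  n0_train <- sum(labels[split$train_indices] == 0)
  counts0 <- vapply(fp$folds, function(f) sum(labels[f] == 0), numeric(1))
  expect_true(all(counts0 %in% c(floor(n0_train / 5), ceiling(n0_train / 5))))
  # 45 training samples -> five folds of 9
  fp2 <- make_fold_plan(1:45, 5, rep(0:1, length.out = 60), seed = 1)
  expect_equal(lengths(fp2$folds), rep(9L, 5), ignore_attr = TRUE)
  expect_error(make_fold_plan(split$train_indices, 60, labels, seed = 1), "exceeds")
})

test_that("split proportions match the benchmark percentage table", {
  expect_equal(compute_split_proportions(72, 17, 5),
               c(calib = 61.1, valid = 15.3, test = 23.6))
  expect_equal(compute_split_proportions(62, 17, 5),
               c(calib = 58.1, valid = 14.5, test = 27.4))
  expect_equal(compute_split_proportions(215, 60, 5),
               c(calib = 57.7, valid = 14.4, test = 27.9))
  expect_equal(compute_split_proportions(203, 58, 5),
               c(calib = 57.1, valid = 14.3, test = 28.6))
  expect_equal(compute_split_proportions(10, 0, 5),
               c(calib = 80.0, valid = 20.0, test = 0.0))
  expect_error(compute_split_proportions(10, 10, 5), "smaller")
})
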