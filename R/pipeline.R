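#' Run configuration for a full experiment
#'
#' Collects everything a run needs: the data (an `expression_matrix`, a
#' file path, or a [synth_spec()]), the kernel model, split sizes, fold
#' count, the component-retention threshold, swarm overrides and seeds.
#'
#' @param data An `expression_matrix`, a `synth_spec`, or a file path
#'   (read via [read_expression_table()]; see `label_column`/`label_file`).
#' @param model_kind `"linear"`, `"polynomial"`, `"gaussian"` or `"lgp"`.
#' @param n_test Test-set size; either an integer count or a fraction in
#'   (0, 1) of the sample count.
#' @param k_folds Cross-validation folds, default 5.
#' @param ppv_threshold Cumulative variance fraction for PCA retention,
#'   default 0.95.
#' @param normalization `"global"` (normalize the full matrix before
#'   splitting) or `"train_fitted"` (fit min-max on the training set,
#'   apply with clipping to the test set).
#' @param n_particles,max_iters Swarm overrides; defaults 10 x D and 50.
#' @param fitness_metric `"accuracy"` (mean CV accuracy, default) or
#'   `"g_mean"`.
#' @param strict_psd Treat an indefinite final training Gram matrix as an
#'   error instead of a warning.
#' @param stratified Stratify the train/test split, default TRUE.
#' @param seed_split,seed_folds,seed_pso Seeds for the three sources of
#'   randomness.
#' @param label_column,label_file Passed to [read_expression_table()] when
#'   `data` is a path.
#' @return A `run_config` list.
#' @export
run_config <- function(data, model_kind = "lgp", n_test = 0.25, k_folds = 5,
                       ppv_threshold = 0.95,
                       normalization = c("global", "train_fitted"),
                       n_particles = NULL, max_iters = 50,
                       fitness_metric = c("accuracy", "g_mean"),
                       strict_psd = FALSE, stratified = TRUE,
                       seed_split = 1, seed_folds = 2, seed_pso = 3,
                       label_column = NULL, label_file = NULL) {
  if (k_folds < 2) stop("k_folds must be >= 2")
  structure(
    list(data = data, model_kind = model_kind, n_test = n_test,
         k_folds = as.integer(k_folds), ppv_threshold = ppv_threshold,
         normalization = match.arg(normalization),
         n_particles = n_particles, max_iters = as.integer(max_iters),
         fitness_metric = match.arg(fitness_metric),
         strict_psd = strict_psd, stratified = stratified,
         seed_split = as.integer(seed_split),
         seed_folds = as.integer(seed_folds),
         seed_pso = as.integer(seed_pso),
         label_column = label_column, label_file = label_file),
    class = "run_config"
  )
}

#' Mean cross-validated accuracy of one parameter set
#'
#' The swarm's objective: for each fold, train the multiclass SVM on the
#' calibration folds' PCA scores (Gram matrix under the given kernel) and
#' score the held-out fold through the cross Gram matrix; return the mean
#' over folds of the chosen metric.
#'
#' @param X Normalized training matrix whose rows correspond, in order, to
#'   the sample indices appearing in `fold_plan` (i.e. `X[i, ]` is the
#'   sample with index `sort(unlist(fold_plan$folds))[i]`), or the full
#'   matrix indexed directly by those indices — see `rows_are_indices`.
#' @param labels Label codes aligned with `X`'s rows (same convention).
#' @param fold_plan A [make_fold_plan()] result.
#' @param C Penalty parameter.
#' @param params A [kernel_params()].
#' @param ppv_threshold PCA retention threshold, default 0.95.
#' @param prep Optional precomputed [cv_fold_scores()] object; when given,
#'   `X`, `labels` and `ppv_threshold` are ignored.
#' @param metric `"accuracy"` or `"g_mean"`.
#' @return Mean metric over the k folds.
#' @export
cv_fitness <- function(X = NULL, labels = NULL, fold_plan = NULL, C, params,
                       ppv_threshold = 0.95, prep = NULL,
                       metric = c("accuracy", "g_mean")) {
  metric <- match.arg(metric)
  if (is.null(prep)) {
    prep <- cv_fold_scores(X, labels, fold_plan, ppv_threshold)
  }
  vals <- vapply(prep$folds, function(f) {
    present <- sort(unique(f$y_calib))
    if (length(present) < 2) {
      warning("calibration folds contain a single class; fold skipped")
      return(NA_real_)
    }
    if (!all(f$y_valid %in% present)) {
      warning("validation fold contains a class absent from calibration")
    }
    # a hybrid parameter set whose Gaussian envelope is unbounded on this
    # fold's scores (odd degree, negative polynomial base) is infeasible
    if (!kernel_bounded(f$scores_calib, params = params) ||
        !kernel_bounded(f$scores_valid, f$scores_calib, params = params)) {
      return(-Inf)
    }
    K <- gram_matrix(f$scores_calib, params = params)
    Kx <- gram_matrix(f$scores_valid, f$scores_calib, params = params)
    if (any(!is.finite(K)) || any(!is.finite(Kx))) return(-Inf)
    model <- train_mcsvm(K, f$y_calib, C, warn_indefinite = FALSE)
    pred <- predict_mcsvm(model, Kx)
    if (metric == "accuracy") {
      mean(pred == f$y_valid)
    } else {
      multiclass_g_mean(confusion(f$y_valid, pred, classes = present))
    }
  }, numeric(1))
  if (all(is.na(vals))) stop("all folds failed")
  mean(vals, na.rm = TRUE)
}

#' Per-fold PCA scores
#'
#' Worker behind [cv_fitness()]: fits the leakage-free per-fold PCA once.
#'
#' @inheritParams cv_fitness
#' @return A `cv_prep` list with one entry per fold: `scores_calib`,
#'   `scores_valid`, `y_calib`, `y_valid`, `k_components`.
#' @export
cv_fold_scores <- function(X, labels, fold_plan, ppv_threshold = 0.95) {
  all_idx <- sort(unlist(fold_plan$folds))
  # rows of X may be the full original matrix or just the training rows
  row_of <- if (nrow(X) == length(labels) && nrow(X) >= max(all_idx)) {
    function(i) i
  } else {
    function(i) match(i, all_idx)
  }
  folds <- lapply(fold_plan$folds, function(f) {
    calib_idx <- setdiff(all_idx, f)
    Xc <- X[row_of(calib_idx), , drop = FALSE]
    Xv <- X[row_of(f), , drop = FALSE]
    model <- fit_pca(Xc, ppv_threshold)
    list(
      scores_calib = pca_transform(model, Xc),
      scores_valid = pca_transform(model, Xv),
      y_calib = labels[row_of(calib_idx)],
      y_valid = labels[row_of(f)],
      k_components = model$k
    )
  })
  structure(list(folds = folds, ppv_threshold = ppv_threshold), class = "cv_prep")
}

resolve_data <- function(config) {
  d <- config$data
  if (inherits(d, "expression_matrix")) return(d)
  if (inherits(d, "synth_spec")) return(generate_dataset(d))
  if (is.character(d) && length(d) == 1) {
    return(read_expression_table(d, label_column = config$label_column,
                                 label_file = config$label_file))
  }
  stop("config$data must be an expression_matrix, synth_spec, or file path")
}

#' Run the full optimization and evaluation pipeline
#'
#' Executes the end-to-end procedure: normalize, split into train/test,
#' fix the 5-fold plan, run the particle swarm over the model's search
#' space with the per-fold-PCA cross-validated accuracy as the objective,
#' refit PCA on the whole training set, train the final multiclass SVM
#' with the best parameters, and score the held-out test set with the
#' imbalance-aware metrics (weighted accuracy, macro F-score, G-mean).
#'
#' @param config A [run_config()].
#' @return A `run_report`: list with `best_C`, `best_params`,
#'   `cv_fitness` (best swarm objective), `cv_fold_metrics` (per-fold
#'   values at the optimum), `cv_components` (retained components per
#'   fold), `final_components`, `confusion` (test confusion matrix),
#'   `metrics` (accuracy, f_score, g_mean), `psd` (PSD check of the final
#'   training Gram), `history` (swarm trace), `n_evals`, `seeds`,
#'   `n_train`, `n_test`, `model_kind`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  em <- resolve_data(config)
  M <- nrow(em$values)
  n_test <- if (config$n_test < 1) round(config$n_test * M) else as.integer(config$n_test)

  if (config$normalization == "global") {
    em <- minmax_normalize(em, mode = "global")$data
    split <- split_train_test(em$labels, n_test, config$seed_split, config$stratified)
    X_train <- em$values[split$train_indices, , drop = FALSE]
    X_test <- em$values[split$test_indices, , drop = FALSE]
  } else {
    split <- split_train_test(em$labels, n_test, config$seed_split, config$stratified)
    em_train <- expression_subset(em, split$train_indices)
    norm <- minmax_normalize(em_train, mode = "train_fitted")
    X_train <- norm$data$values
    X_test_raw <- em$values[split$test_indices, , drop = FALSE]
    X_test <- apply_norm_stats(X_test_raw, norm$stats)
  }
  y_train <- em$labels[split$train_indices]
  y_test <- em$labels[split$test_indices]

  fold_plan <- make_fold_plan(split$train_indices, config$k_folds,
                              em$labels, config$seed_folds)
  # relabel fold indices to positions within the training block
  fold_local <- fold_plan
  fold_local$folds <- lapply(fold_plan$folds, function(f) match(f, split$train_indices))

  prep <- cv_fold_scores(X_train, y_train, fold_local, config$ppv_threshold)

  space <- build_search_space(config$model_kind)
  D <- nrow(space)
  cfg <- swarm_config(
    D,
    n_particles = if (is.null(config$n_particles)) 10 * D else config$n_particles,
    max_iters = config$max_iters,
    seed = config$seed_pso
  )
  fitness <- function(C, params) {
    cv_fitness(C = C, params = params, prep = prep, metric = config$fitness_metric)
  }
  opt <- pso_optimize(space, fitness, cfg)

  # per-fold metrics at the optimum
  fold_metrics <- vapply(prep$folds, function(f) {
    K <- gram_matrix(f$scores_calib, params = opt$best_params)
    m <- train_mcsvm(K, f$y_calib, opt$best_C, warn_indefinite = FALSE)
    Kx <- gram_matrix(f$scores_valid, f$scores_calib, params = opt$best_params)
    mean(predict_mcsvm(m, Kx) == f$y_valid)
  }, numeric(1))

  # final model: PCA on the whole training set, SVM with best parameters
  final_pca <- fit_pca(X_train, config$ppv_threshold)
  S_train <- pca_transform(final_pca, X_train)
  S_test <- pca_transform(final_pca, X_test)
  if (!kernel_bounded(S_train, params = opt$best_params) ||
      !kernel_bounded(S_test, S_train, params = opt$best_params)) {
    warning("selected kernel parameters are unbounded on the full training ",
            "scores (fold-feasible but not train-feasible); results may be ",
            "numerically fragile")
  }
  K_final <- gram_matrix(S_train, params = opt$best_params)
  if (any(!is.finite(K_final))) {
    stop("final training Gram matrix has non-finite entries under the ",
         "selected kernel parameters")
  }
  # looser gate than the standalone check: flag genuine Mercer violations,
  # not eigensolver roundoff on a few-hundred-row matrix
  psd <- check_psd(K_final, tol = 1e-6)
  if (!psd$is_psd) {
    msg <- sprintf("final training Gram matrix is indefinite (min eigenvalue %.4g)",
                   psd$min_eigenvalue)
    if (config$strict_psd) stop(msg) else warning(msg)
  }
  final_model <- train_mcsvm(K_final, y_train, opt$best_C, warn_indefinite = FALSE)
  K_cross <- gram_matrix(S_test, S_train, params = opt$best_params)
  y_pred <- predict_mcsvm(final_model, K_cross)
  cm <- confusion(y_test, y_pred, classes = seq_along(em$class_names) - 1L)

  structure(
    list(
      model_kind = config$model_kind,
      best_C = opt$best_C,
      best_params = opt$best_params,
      cv_fitness = opt$best_fitness,
      cv_fold_metrics = fold_metrics,
      cv_components = vapply(prep$folds, `[[`, integer(1), "k_components"),
      final_components = final_pca$k,
      confusion = cm,
      metrics = list(
        accuracy = weighted_accuracy(cm),
        f_score = multiclass_f_score(cm),
        g_mean = multiclass_g_mean(cm)
      ),
      psd = psd,
      history = opt$history,
      n_evals = opt$n_evals,
      n_particles = cfg$n_particles,
      seeds = c(split = config$seed_split, folds = config$seed_folds,
                pso = config$seed_pso),
      n_train = length(split$train_indices),
      n_test = length(split$test_indices)
    ),
    class = "run_report"
  )
}

expression_subset <- function(em, idx) {
  em$values <- em$values[idx, , drop = FALSE]
  em$labels <- em$labels[idx]
  em$sample_ids <- em$sample_ids[idx]
  em
}

apply_norm_stats <- function(X, stats) {
  rng <- stats$max - stats$min
  out <- sweep(X, 2, stats$min, "-")
  out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/")
  out[, rng == 0] <- 0
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: %s kernel, %d train / %d test samples\n",
              x$model_kind, x$n_train, x$n_test))
  cat(sprintf("  swarm: %d particles, %d evaluations; best CV fitness %.4f\n",
              x$n_particles, x$n_evals, x$cv_fitness))
  cat(sprintf("  retained components: CV %s; final %d\n",
              paste(x$cv_components, collapse = "/"), x$final_components))
  cat(sprintf("  test metrics: accuracy %.4f, F-score %.4f, G-mean %.4f\n",
              x$metrics$accuracy, x$metrics$f_score, x$metrics$g_mean))
  if (!x$psd$is_psd) {
    cat(sprintf("  warning: indefinite training Gram (min eigenvalue %.4g)\n",
                x$psd$min_eigenvalue))
  }
  invisible(x)
}

#' Write a run report as delimited text
#'
#' Emits a TSV metrics row and the confusion matrix, sufficient to
#' recompute every reported metric.
#'
#' @param report A `run_report`.
#' @param path Output TSV path for the metrics row.
#' @param confusion_path Optional TSV path for the confusion matrix.
#' @return Invisibly, `path`.
#' @export
write_run_report <- function(report, path, confusion_path = NULL) {
  row <- data.frame(
    model_kind = report$model_kind,
    C = report$best_C,
    cv_fitness = report$cv_fitness,
    accuracy = report$metrics$accuracy,
    f_score = report$metrics$f_score,
    g_mean = report$metrics$g_mean,
    final_components = report$final_components,
    n_train = report$n_train,
    n_test = report$n_test
  )
  data.table::fwrite(row, path, sep = "\t")
  if (!is.null(confusion_path)) {
    cmdf <- as.data.frame.matrix(unclass(report$confusion))
    cmdf <- cbind(true_class = rownames(cmdf), cmdf)
    data.table::fwrite(cmdf, confusion_path, sep = "\t")
  }
  invisible(path)
}
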