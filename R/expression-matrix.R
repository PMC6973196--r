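#' Construct an expression matrix
#'
#' The central container of the package: a samples x genes numeric matrix
#' together with an integer class label per sample. Labels are stored as
#' 0-based integer codes (`0 .. C-1`); `class_names` records the original
#' label of each code, in first-seen order.
#'
#' @param values Numeric matrix, samples in rows, genes in columns. Row and
#'   column names, when present, are used as sample and gene identifiers.
#' @param labels Integer vector of class codes (`0 .. C-1`), one per sample,
#'   or any atomic vector which is then encoded in first-seen order.
#' @param class_names Character vector naming each class code. Required when
#'   `labels` is already an integer code vector; inferred otherwise.
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `labels` (0-based integer), `class_names`, `sample_ids`,
#'   `gene_ids`.
#' @export
expression_matrix <- function(values, labels, class_names = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at sample %d, gene %d", bad[1], bad[2]))
  }
  if (length(labels) != nrow(values)) {
    stop(sprintf("%d labels for %d samples", length(labels), nrow(values)))
  }
  if (is.null(class_names)) {
    lev <- unique(as.character(labels))
    codes <- match(as.character(labels), lev) - 1L
    class_names <- lev
  } else {
    codes <- as.integer(labels)
    if (any(codes < 0L) || any(codes >= length(class_names))) {
      stop("integer labels must lie in 0 .. length(class_names)-1")
    }
  }
  if (!all((seq_along(class_names) - 1L) %in% codes)) {
    stop("every class code 0..C-1 must appear at least once")
  }
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("sample_", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("gene_", seq_len(ncol(values)))
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate sample IDs")
  }
  structure(
    list(
      values = values,
      labels = codes,
      class_names = as.character(class_names),
      sample_ids = rownames(values),
      gene_ids = colnames(values)
    ),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "expression_matrix: %d samples x %d genes, %d classes\n",
    nrow(x$values), ncol(x$values), length(x$class_names)
  ))
  tab <- table(factor(x$labels, levels = seq_along(x$class_names) - 1L,
                      labels = x$class_names))
  cat("class counts:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Number of classes in an expression matrix
#' @param em An `expression_matrix`.
#' @return Integer class count.
#' @export
n_classes <- function(em) length(em$class_names)

#' Read a delimited expression table
#'
#' Reads a CSV/TSV expression table into the canonical samples x genes layout,
#' regardless of on-disk orientation. Labels come either from a named column
#' of the table (`samples_in_rows` only) or from a sidecar single-column file
#' aligned with the samples. Non-numeric or missing expression cells are
#' rejected with their location.
#'
#' @param path Path to a delimited text file with a header row; the first
#'   column holds identifiers. Delimiter is auto-detected (`.csv` -> comma,
#'   `.tsv`/`.txt` -> tab).
#' @param orientation `"samples_in_rows"` (default) or `"genes_in_rows"`.
#' @param label_column Name of the label column inside the table.
#' @param label_file Path to a sidecar file with one label per sample
#'   (single column, optional header `label`).
#'
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path,
                                  orientation = c("samples_in_rows", "genes_in_rows"),
                                  label_column = NULL,
                                  label_file = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(label_column) && is.null(label_file)) {
    stop("labels are required: supply `label_column` or `label_file`")
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          colClasses = list(character = 1), data.table = FALSE,
                          na.strings = NULL)
  ids <- as.character(dt[[1]])
  dt <- dt[, -1, drop = FALSE]

  labels <- NULL
  if (!is.null(label_column)) {
    if (orientation != "samples_in_rows") {
      stop("`label_column` requires orientation = \"samples_in_rows\"")
    }
    if (!label_column %in% names(dt)) {
      stop(sprintf("label column '%s' not found", label_column))
    }
    labels <- dt[[label_column]]
    dt <- dt[, setdiff(names(dt), label_column), drop = FALSE]
  }

  mat <- as.matrix(dt)
  num <- suppressWarnings(matrix(as.numeric(mat), nrow(mat), ncol(mat),
                                 dimnames = dimnames(mat)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf(
      "non-numeric or missing value '%s' at row '%s', column '%s'",
      mat[bad[1], bad[2]], ids[bad[1]], colnames(mat)[bad[2]]
    ))
  }
  rownames(num) <- ids

  if (orientation == "genes_in_rows") {
    num <- t(num)
  }
  if (anyDuplicated(rownames(num))) {
    stop(sprintf("duplicate sample IDs (e.g. '%s')",
                 rownames(num)[duplicated(rownames(num))][1]))
  }
  if (!is.null(label_file)) {
    lab_dt <- data.table::fread(label_file, header = "auto", data.table = FALSE)
    labels <- lab_dt[[ncol(lab_dt)]]
    if (length(labels) != nrow(num)) {
      stop(sprintf("label file has %d entries for %d samples",
                   length(labels), nrow(num)))
    }
  }
  if (anyNA(labels) || any(labels == "")) {
    stop(sprintf("missing label for sample '%s'",
                 rownames(num)[which(is.na(labels) | labels == "")[1]]))
  }
  expression_matrix(num, labels)
}

#' Write an expression matrix and its labels to delimited text
#'
#' Companion writer to [read_expression_table()]: emits a samples-in-rows
#' table and a sidecar label file re-readable by the loader.
#'
#' @param em An `expression_matrix`.
#' @param path Output path for the expression table (`.csv` or `.tsv`).
#' @param label_file Output path for the one-column label file.
#' @return Invisibly, `path`.
#' @export
write_expression_table <- function(em, path, label_file) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(sample_id = em$sample_ids, em$values, check.names = FALSE)
  data.table::fwrite(df, path, sep = sep)
  data.table::fwrite(
    data.frame(label = em$class_names[em$labels + 1L]), label_file, sep = sep
  )
  invisible(path)
}

#' Min-max normalization of expression values
#'
#' Linearly maps each gene column from its observed `[min, max]` onto
#' `[0, 1]`. In `train_fitted` mode, statistics fitted on training data can
#' be re-applied to held-out data, in which case out-of-range values are
#' clipped to `[0, 1]`. Constant genes (`max == min`) map to 0.
#'
#' @param em An `expression_matrix`.
#' @param mode `"global"` (fit and apply on `em` itself) or `"train_fitted"`
#'   (fit here, intended for later re-application elsewhere).
#' @param stats Optional `norm_stats` from a previous call; when supplied its
#'   min/max are applied instead of refitting, with clipping.
#' @return List with `data` (normalized `expression_matrix`) and `stats`
#'   (a `norm_stats` object: per-gene `min`, `max`, and the `mode`).
#' @export
minmax_normalize <- function(em, mode = c("global", "train_fitted"), stats = NULL) {
  mode <- match.arg(mode)
  X <- em$values
  if (is.null(stats)) {
    stats <- structure(
      list(min = apply(X, 2, min), max = apply(X, 2, max), mode = mode),
      class = "norm_stats"
    )
    clip <- FALSE
  } else {
    if (length(stats$min) != ncol(X)) {
      stop(sprintf("norm stats cover %d genes, data has %d",
                   length(stats$min), ncol(X)))
    }
    clip <- TRUE
  }
  rng <- stats$max - stats$min
  out <- sweep(X, 2, stats$min, "-")
  out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/")
  out[, rng == 0] <- 0
  if (clip) {
    out[out < 0] <- 0
    out[out > 1] <- 1
  }
  em$values <- out
  list(data = em, stats = stats)
}

#' Random train/test split
#'
#' Splits samples into disjoint train and test index sets. Stratified by
#' default: per-class test counts follow class prevalence with
#' largest-remainder rounding, so minority classes are represented in the
#' test set whenever arithmetic allows.
#'
#' @param labels Integer class vector (0-based codes) of length M.
#' @param n_test Number of test samples, `0 <= n_test < M`.
#' @param seed Integer seed; the split is reproducible given the seed.
#' @param stratified Logical, default `TRUE`.
#' @return A `dataset_split`: list with `train_indices`, `test_indices`
#'   (1-based, disjoint, jointly covering `1..M`), and `seed`.
#' @export
split_train_test <- function(labels, n_test, seed, stratified = TRUE) {
  M <- length(labels)
  if (n_test < 0 || n_test >= M) {
    stop(sprintf("n_test must satisfy 0 <= n_test < %d", M))
  }
  test_idx <- integer(0)
  if (n_test > 0) {
    if (stratified) {
      cls <- sort(unique(labels))
      counts <- vapply(cls, function(c) sum(labels == c), integer(1))
      quota <- n_test * counts / M
      base <- floor(quota)
      rem <- n_test - sum(base)
      if (rem > 0) {
        frac_order <- order(quota - base, decreasing = TRUE)
        base[frac_order[seq_len(rem)]] <- base[frac_order[seq_len(rem)]] + 1
      }
      if (any(base >= counts & counts > 0)) {
        stop("stratified split would place an entire class in the test set; ",
             "use stratified = FALSE or reduce n_test")
      }
      test_idx <- withr::with_seed(seed, {
        unlist(lapply(seq_along(cls), function(i) {
          pool <- which(labels == cls[i])
          sample(pool, base[i])
        }))
      })
    } else {
      test_idx <- withr::with_seed(seed, sample.int(M, n_test))
    }
  }
  test_idx <- sort(test_idx)
  structure(
    list(
      train_indices = setdiff(seq_len(M), test_idx),
      test_indices = test_idx,
      seed = seed
    ),
    class = "dataset_split"
  )
}

#' Stratified k-fold plan over a training set
#'
#' Partitions training indices into `k` folds, stratified by class, with
#' fold sizes differing by at most one.
#'
#' @param train_indices Integer indices of the training samples.
#' @param k Number of folds (>= 2).
#' @param labels Full class vector; only `labels[train_indices]` is used.
#' @param seed Integer seed.
#' @return A `fold_plan`: list with `folds` (list of k index vectors),
#'   `k`, `seed`.
#' @export
make_fold_plan <- function(train_indices, k, labels, seed) {
  n <- length(train_indices)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop(sprintf("k = %d exceeds the %d training samples", k, n))
  y <- labels[train_indices]
  ord <- withr::with_seed(seed, {
    unlist(lapply(sort(unique(y)), function(c) {
      pool <- train_indices[y == c]
      if (length(pool) > 1) sample(pool) else pool
    }))
  })
  fold_id <- rep_len(seq_len(k), n)
  folds <- split(ord, fold_id)
  names(folds) <- NULL
  structure(list(folds = folds, k = k, seed = seed), class = "fold_plan")
}

#' Calibration/validation/test percentage proportions
#'
#' Given a dataset of `n_total` samples, a held-out test count and a fold
#' count `k`, reports the percentage of samples used for calibration (k-1
#' folds), validation (one fold, floored when the training count is not
#' divisible by k) and testing, each rounded to one decimal.
#'
#' @param n_total Total sample count.
#' @param n_test Test sample count (`< n_total`).
#' @param k Fold count (>= 2).
#' @return Named numeric vector `c(calib, valid, test)` in percent.
#' @export
compute_split_proportions <- function(n_total, n_test, k) {
  if (n_test >= n_total) stop("n_test must be smaller than n_total")
  if (k < 2) stop("k must be >= 2")
  n_train <- n_total - n_test
  n_fold <- floor(n_train / k)
  c(
    calib = round(100 * (n_train - n_fold) / n_total, 1),
    valid = round(100 * n_fold / n_total, 1),
    test = round(100 * n_test / n_total, 1)
  )
}
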