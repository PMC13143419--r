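# Gradient-boosted-tree modeling layer.
#
# The boosting backend is a pluggable contract (fit with sample weights,
# predict scores); the default backend is xgboost with histogram trees.  All
# backend hyperparameters beyond the tree count are left at the backend's
# defaults.

#' Model configuration
#'
#' @param n_trees Number of boosting rounds (default 500).
#' @param class_weighting Apply class weights inversely proportional to the
#'   positive-class frequency on binary tasks (default `TRUE`)?
#' @param seed Integer seed passed to the backend.
#' @param backend Backend name; `"xgboost"` is the only built-in.
#' @return A `model_config` list.  Objectives are chosen per task type:
#'   log-loss for binary tasks, mean absolute error for regression.
#' @export
#' @examples
#' model_config()
model_config <- function(n_trees = 500L, class_weighting = TRUE, seed = 0L,
                         backend = "xgboost") {
  n_trees <- as.integer(n_trees)
  if (is.na(n_trees) || n_trees < 1) {
    pep_abort("n_trees must be a positive integer", "pep_config_error")
  }
  structure(list(n_trees = n_trees,
                 class_weighting = isTRUE(class_weighting),
                 seed = as.integer(seed), backend = backend,
                 objective = c(binary = "log-loss", regression = "mae")),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config: %d trees, class weighting %s, seed %d (%s)>\n",
              x$n_trees, if (x$class_weighting) "on" else "off", x$seed,
              x$backend))
  invisible(x)
}

#' Class weights inversely proportional to the positive-class frequency
#'
#' @param labels Binary label vector containing both classes.
#' @return Named numeric vector `c(w_pos = n_neg / n_pos, w_neg = 1)`.
#' @export
#' @examples
#' class_weights(c(0, 0, 0, 0, 0, 0, 0, 0, 1, 1)) # w_pos = 4
class_weights <- function(labels) {
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    pep_abort("labels must be binary (0/1)", "pep_config_error")
  }
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) {
    pep_abort("degenerate labels: both classes must be present",
              "pep_degenerate_error")
  }
  c(w_pos = n_neg / n_pos, w_neg = 1)
}

features_matrix <- function(features) {
  if (inherits(features, "pep_features")) return(features$matrix)
  if (inherits(features, "dgCMatrix") || is.matrix(features)) return(features)
  if (is.data.frame(features)) return(as.matrix(features))
  pep_abort("features must be a pep_features object or a matrix",
            "pep_config_error")
}

# xgboost backend (histogram trees, single thread for reproducibility)
fit_one_task <- function(x, y, task_type, config) {
  w <- rep(1, length(y))
  if (task_type == "binary") {
    cw <- class_weights(y) # errors on degenerate columns
    w[y == 1] <- cw[["w_pos"]]
    params <- list(objective = "binary:logistic", tree_method = "hist",
                   nthread = 1, seed = config$seed)
  } else {
    params <- list(objective = "reg:absoluteerror", tree_method = "hist",
                   nthread = 1, seed = config$seed)
  }
  if (!config$class_weighting) w <- rep(1, length(y))
  dtrain <- xgboost::xgb.DMatrix(x, label = y, weight = w, nthread = 1)
  xgboost::xgb.train(params = params, data = dtrain,
                     nrounds = config$n_trees, verbose = 0)
}

#' Fit one gradient-boosted model per target column
#'
#' Trains a separate boosted-tree model for each task (column of `targets`):
#' log-loss objective with optional class weighting for binary tasks, MAE
#' objective for regression tasks.  A degenerate task column (single class)
#' is recorded as a per-task error; the remaining tasks still train.
#'
#' @param features A `pep_features` object or numeric/sparse matrix (rows =
#'   samples).
#' @param targets Vector, matrix or data frame of targets (columns = tasks).
#' @param task_types `"binary"`/`"regression"` per task; inferred when `NULL`.
#' @param config A [model_config()].
#' @return A `pep_model` bundle with one fitted model per task, the config
#'   and task metadata.
#' @export
fit_peptide_model <- function(features, targets, task_types = NULL,
                              config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  x <- features_matrix(features)
  targets <- as.matrix(targets)
  if (nrow(x) != nrow(targets)) {
    pep_abort("features and targets must have the same number of rows",
              "pep_config_error")
  }
  if (nrow(x) < 2) {
    pep_abort("need at least 2 rows to train", "pep_config_error")
  }
  k <- ncol(targets)
  tasks <- colnames(targets) %||% paste0("task", seq_len(k))
  task_types <- task_types %||% infer_task_types(targets)
  models <- vector("list", k)
  errors <- vector("list", k)
  names(models) <- names(errors) <- tasks
  for (j in seq_len(k)) {
    fit <- tryCatch(fit_one_task(x, as.numeric(targets[, j]), task_types[j],
                                 config),
                    pep_degenerate_error = function(e) e)
    if (inherits(fit, "error")) {
      errors[[j]] <- conditionMessage(fit)
      warn(sprintf("task '%s' not trained: %s", tasks[j], errors[[j]]))
    } else {
      models[[j]] <- fit
    }
  }
  if (all(vapply(models, is.null, logical(1)))) {
    pep_abort("degenerate labels: no task could be trained",
              "pep_degenerate_error")
  }
  structure(list(models = models, tasks = tasks, task_types = task_types,
                 errors = errors, config = config, n_features = ncol(x)),
            class = "pep_model")
}

#' @export
print.pep_model <- function(x, ...) {
  ok <- sum(!vapply(x$models, is.null, logical(1)))
  cat(sprintf("<pep_model: %d/%d tasks trained, %d trees, %d features>\n",
              ok, length(x$tasks), x$config$n_trees, x$n_features))
  invisible(x)
}

#' Predict per-task scores
#'
#' @param object A `pep_model`.
#' @param features Features with the same column layout as at training.
#' @param ... Unused.
#' @return Tibble with one column per task: probabilities for binary tasks,
#'   values for regression; `NA` for tasks that failed to train.
#' @export
predict.pep_model <- function(object, features, ...) {
  x <- features_matrix(features)
  cols <- lapply(seq_along(object$tasks), function(j) {
    m <- object$models[[j]]
    if (is.null(m)) return(rep(NA_real_, nrow(x)))
    predict(m, xgboost::xgb.DMatrix(x, nthread = 1))
  })
  names(cols) <- object$tasks
  as_tibble(cols)
}

#' @rdname fit_peptide_model
#' @param x A `pep_model`.
#' @param ... Unused.
#' @export
tidy.pep_model <- function(x, ...) {
  tibble(task = x$tasks, task_type = unname(x$task_types),
         trained = unname(!vapply(x$models, is.null, logical(1))),
         error = unname(vapply(x$errors, function(e) e %||% NA_character_,
                               character(1))),
         n_trees = x$config$n_trees,
         objective = unname(x$config$objective[x$task_types]))
}

#' @rdname fit_peptide_model
#' @export
glance.pep_model <- function(x, ...) {
  tibble(n_tasks = length(x$tasks),
         n_trained = sum(!vapply(x$models, is.null, logical(1))),
         n_trees = x$config$n_trees,
         n_features = x$n_features,
         class_weighting = x$config$class_weighting,
         seed = x$config$seed,
         backend = x$config$backend)
}

#' Amino-acid n-gram count features
#'
#' Bag-of-words features on the sequences themselves: 20 unigram and 400
#' bigram count columns in fixed alphabetical order (the classical baseline);
#' higher orders (e.g. trigrams) can be added for motif-sensitive baselines.
#'
#' @param data Data frame with a sequence column, or character vector.
#' @param orders Integer n-gram orders to include (default `1:2`).
#' @param seq_col Sequence column name.
#' @return A sparse matrix (rows = sequences) with named columns.
#' @export
#' @examples
#' m <- aa_count_features("GGA")
#' m[1, c("G", "A", "GG", "GA")]
aa_count_features <- function(data, orders = 1:2, seq_col = "sequence") {
  rs <- resolve_sequences(data, seq_col)
  seqs <- validate_sequences(rs$seqs)
  cols <- unlist(lapply(sort(orders), function(k) {
    apply(do.call(expand.grid,
                  rev(rep(list(AA_ALPHABET), k)))[, k:1, drop = FALSE],
          1, paste, collapse = "")
  }))
  col_index <- setNames(seq_along(cols), cols)
  triplets <- lapply(seq_along(seqs), function(i) {
    chars <- strsplit(seqs[i], "")[[1]]
    grams <- unlist(lapply(sort(orders), function(k) {
      if (length(chars) < k) return(character(0))
      vapply(seq_len(length(chars) - k + 1),
             function(p) paste(chars[p:(p + k - 1)], collapse = ""),
             character(1))
    }))
    tab <- table(grams)
    list(j = unname(col_index[names(tab)]), x = as.numeric(tab))
  })
  nnz <- vapply(triplets, function(t) length(t$j), integer(1))
  Matrix::sparseMatrix(
    i = rep(seq_along(seqs), nnz),
    j = unlist(lapply(triplets, `[[`, "j"), use.names = FALSE),
    x = unlist(lapply(triplets, `[[`, "x"), use.names = FALSE),
    dims = c(length(seqs), length(cols)),
    dimnames = list(rs$ids, cols))
}

#' Append a sequence-length column to a binary feature matrix
#'
#' The control representation for ablations: binary fingerprints augmented
#' with the residue count, testing whether counts merely encode size.
#' Calling it twice on the same matrix is an error.
#'
#' @param features Binary feature matrix (or `pep_features`).
#' @param data Sequences aligned with the feature rows (data frame or
#'   character vector).
#' @param seq_col Sequence column name.
#' @return The matrix with one extra `seq_length` column.
#' @export
binary_plus_length <- function(features, data, seq_col = "sequence") {
  x <- features_matrix(features)
  rs <- resolve_sequences(data, seq_col)
  seqs <- validate_sequences(rs$seqs)
  if (nrow(x) != length(seqs)) {
    pep_abort("feature rows and sequences must align", "pep_config_error")
  }
  if ("seq_length" %in% colnames(x)) {
    pep_abort("features already contain a seq_length column",
              "pep_config_error")
  }
  len <- nchar(seqs)
  out <- cbind(x, seq_length = len)
  base_names <- colnames(x)
  if (is.null(base_names)) {
    base_names <- if (ncol(x) > 0) paste0("bit", seq_len(ncol(x)) - 1L)
      else character(0)
  }
  colnames(out) <- c(base_names, "seq_length")
  out
}
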