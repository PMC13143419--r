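# Evaluation metrics for imbalanced peptide property prediction.

#' Area under the ROC curve
#'
#' Computed by the Mann-Whitney rank formula with mid-rank tie correction, so
#' tied scores contribute 1/2 per discordant-free pair.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1 or logical).
#' @return AUROC in `[0, 1]`, or `NA` with a warning if only one class is
#'   present.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) {
    warn("AUROC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Average precision (area under the precision-recall curve)
#'
#' Non-interpolated average precision with tied scores handled by grouping:
#' descending over distinct score values, each group contributes its recall
#' gain times the precision at the group's end.  With constant scores this
#' reduces to the positive prevalence.
#'
#' @inheritParams auroc
#' @return Average precision in `[0, 1]`, or `NA` if no positives.
#' @export
average_precision <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L)
  if (n_pos == 0) {
    warn("average precision undefined: no positives")
    return(NA_real_)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  grp_tp <- rowsum(y, s, reorder = FALSE)
  grp_n <- rowsum(rep(1L, length(y)), s, reorder = FALSE)
  cum_tp <- cumsum(grp_tp)
  cum_n <- cumsum(grp_n)
  sum((grp_tp / n_pos) * (cum_tp / cum_n))
}

confusion_at <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  labels <- as.integer(labels)
  c(tp = sum(pred == 1 & labels == 1), fp = sum(pred == 1 & labels == 0),
    tn = sum(pred == 0 & labels == 0), fn = sum(pred == 0 & labels == 1))
}

#' Matthews correlation coefficient at a score threshold
#'
#' @inheritParams auroc
#' @param threshold Decision threshold on the scores (default 0.5).
#' @return MCC in `[-1, 1]`; 0 when a marginal is empty.
#' @export
mcc_score <- function(scores, labels, threshold = 0.5) {
  cm <- confusion_at(scores, labels, threshold)
  denom <- sqrt(prod(c(cm["tp"] + cm["fp"], cm["tp"] + cm["fn"],
                       cm["tn"] + cm["fp"], cm["tn"] + cm["fn"])))
  if (denom == 0) return(0)
  unname((cm["tp"] * cm["tn"] - cm["fp"] * cm["fn"]) / denom)
}

#' F1 score at a score threshold
#'
#' @inheritParams mcc_score
#' @return F1 in `[0, 1]`; 0 when there are no predicted or true positives.
#' @export
f1_score <- function(scores, labels, threshold = 0.5) {
  cm <- confusion_at(scores, labels, threshold)
  denom <- 2 * cm["tp"] + cm["fp"] + cm["fn"]
  if (denom == 0) return(0)
  unname(2 * cm["tp"] / denom)
}

#' Mean absolute error
#'
#' @param scores Predicted values.
#' @param targets Observed values.
#' @return MAE.
#' @export
mae <- function(scores, targets) {
  stopifnot(length(scores) == length(targets))
  mean(abs(scores - targets))
}

#' Evaluate predictions against targets, per task
#'
#' Computes AUPRC (average precision), AUROC, MCC and F1 (threshold 0.5) for
#' binary tasks, and MAE for regression tasks; task averages are unweighted
#' means.  A test column with a single class yields `NA` metrics, which are
#' excluded from the averages with a warning.
#'
#' @param scores Numeric vector or matrix/data frame (columns = tasks) of
#'   predicted scores (probabilities for binary tasks).
#' @param targets Vector or matrix/data frame of observed targets, same shape.
#' @param task_types Character vector, one of `"binary"`/`"regression"` per
#'   task; inferred from the targets when `NULL`.
#' @return A `pep_metrics` tibble with columns `task`, `task_type`, `metric`,
#'   `value`.
#' @export
evaluate_predictions <- function(scores, targets, task_types = NULL) {
  scores <- as.matrix(scores)
  targets <- as.matrix(targets)
  if (!all(dim(scores) == dim(targets))) {
    pep_abort("scores and targets must have identical shapes",
              "pep_config_error")
  }
  k <- ncol(scores)
  tasks <- colnames(targets) %||% paste0("task", seq_len(k))
  if (is.null(colnames(targets))) colnames(targets) <- tasks
  task_types <- task_types %||% infer_task_types(targets)
  if (length(task_types) != k) {
    pep_abort("task_types length must match the number of columns",
              "pep_config_error")
  }
  rows <- lapply(seq_len(k), function(j) {
    y <- targets[, j]
    s <- scores[, j]
    if (task_types[j] == "binary") {
      single <- length(unique(y[!is.na(y)])) < 2
      if (single) {
        warn(sprintf(
          "task '%s' has a single class in the test targets; metrics undefined and excluded from averages",
          tasks[j]))
        vals <- c(auprc = NA_real_, auroc = NA_real_, mcc = NA_real_,
                  f1 = NA_real_)
      } else {
        vals <- c(auprc = average_precision(s, y), auroc = auroc(s, y),
                  mcc = mcc_score(s, y), f1 = f1_score(s, y))
      }
    } else {
      vals <- c(mae = mae(s, y))
    }
    tibble(task = tasks[j], task_type = task_types[j],
           metric = names(vals), value = unname(vals))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pep_metrics", class(out))
  out
}

infer_task_types <- function(targets) {
  apply(as.matrix(targets), 2, function(y) {
    if (all(stats::na.omit(y) %in% c(0, 1))) "binary" else "regression"
  })
}

#' Unweighted task averages of a metric report
#'
#' @param x A `pep_metrics` tibble.
#' @param ... Unused.
#' @return One-row tibble with the mean of each metric over the tasks where it
#'   is defined, plus the number of tasks.
#' @export
glance.pep_metrics <- function(x, ...) {
  avg <- x |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  out <- tidyr::pivot_wider(avg, names_from = "metric",
                            values_from = "value")
  out$n_tasks <- length(unique(x$task))
  out
}
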