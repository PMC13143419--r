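# Control experiments: count-versus-binary ablation and the charged-motif
# stress test.

split_train_test <- function(data, test_fraction, seed) {
  n <- nrow(data)
  n_test <- max(1L, round(n * test_fraction))
  idx <- with_seed(seed, sample.int(n, n_test))
  list(train = data[-idx, , drop = FALSE], test = data[idx, , drop = FALSE])
}

#' Count-versus-binary fingerprint ablation
#'
#' For each fingerprint family, evaluates the count variant, the binary
#' variant, and the binary variant augmented with a sequence-length column,
#' on an identical train/test split and seed, and reports metric deltas
#' (count minus binary) alongside the absolute values.
#'
#' @param train,test Data frames with `sequence` and a `label` column.
#' @param families Fingerprint families to ablate (default `"circular"`).
#' @param fp_options Named list of extra [fp_config()] arguments (e.g.
#'   `n_bits`).
#' @param model_config A [model_config()].
#' @param metric Metric used for the reported deltas (default `"mae"` for
#'   regression labels, `"auprc"` for binary).
#' @return A `pep_ablation` tibble: one row per family, variant, task and
#'   metric, with a `delta` attribute table (count minus binary).
#' @export
count_vs_binary_ablation <- function(train, test, families = "circular",
                                     fp_options = list(),
                                     model_config = pepfp::model_config(),
                                     metric = NULL) {
  stopifnot(is.data.frame(train), is.data.frame(test),
            "label" %in% names(train), "label" %in% names(test))
  rows <- list()
  for (fam in families) {
    cfg_count <- do.call(fp_config,
                         c(list(family = fam, variant = "count"), fp_options))
    # count features are computed once; the binary variant is its indicator,
    # so all variants share identical folds
    xtr_count <- featurize(train, cfg_count)
    xte_count <- featurize(test, cfg_count)
    xtr_bin <- indicator_matrix(xtr_count$matrix)
    xte_bin <- indicator_matrix(xte_count$matrix)
    xtr_binlen <- binary_plus_length(xtr_bin, train$sequence)
    xte_binlen <- binary_plus_length(xte_bin, test$sequence)
    variants <- list(count = list(xtr_count, xte_count),
                     binary = list(xtr_bin, xte_bin),
                     binary_length = list(xtr_binlen, xte_binlen))
    for (v in names(variants)) {
      res <- tryCatch({
        fit <- fit_peptide_model(variants[[v]][[1]],
                                 train[, "label", drop = FALSE],
                                 config = model_config)
        scores <- predict(fit, variants[[v]][[2]])
        evaluate_predictions(scores, test[, "label", drop = FALSE],
                             fit$task_types)
      }, pep_degenerate_error = function(e) {
        tibble(task = "label", task_type = NA_character_,
               metric = NA_character_, value = NA_real_,
               error = conditionMessage(e))
      })
      rows[[paste(fam, v)]] <- dplyr::mutate(res, family = fam, variant = v,
                                             .before = 1)
    }
  }
  out <- dplyr::bind_rows(rows)
  ok <- dplyr::filter(out, .data$variant %in% c("count", "binary"),
                      !is.na(.data$metric))
  deltas <- if (nrow(ok) > 0) {
    tidyr::pivot_wider(ok, id_cols = c("family", "task", "metric"),
                       names_from = "variant", values_from = "value") |>
      dplyr::mutate(delta = .data$count - .data$binary)
  } else {
    tibble(family = character(0), task = character(0), metric = character(0),
           count = numeric(0), binary = numeric(0), delta = numeric(0))
  }
  attr(out, "delta") <- deltas
  class(out) <- c("pep_ablation", "tbl_df", "tbl", "data.frame")
  out
}

indicator_matrix <- function(m) {
  out <- m
  out@x <- as.numeric(out@x > 0)
  out <- Matrix::drop0(out)
  out
}

#' Charged-motif stress test
#'
#' Generates a motif-labeled synthetic dataset (e.g. "KKK"/"RRR"), then trains
#' on the identical split (i) the fingerprint model and (ii) a sequence
#' n-gram baseline whose features include trigram counts, so the motif is
#' directly observable to the baseline but only indirectly (through local
#' atom neighborhoods) to the fingerprints.  Motif recognition is an
#' order-dependent, long-range task on the molecular graph, which is why it
#' is hard for short-range fingerprints.
#'
#' @param spec A [synthetic_spec()] with `label_rule = "motif"` and motifs of
#'   length >= 3.
#' @param fp_config An [fp_config()].
#' @param model_config A [model_config()].
#' @param test_fraction Held-out fraction (default 0.25).
#' @param ngram_orders n-gram orders for the baseline (default `1:3`).
#' @return A `pep_motif_test` tibble with one row per model, task and metric
#'   (paired on the same split).
#' @export
motif_stress_test <- function(spec, fp_config = pepfp::fp_config(),
                              model_config = pepfp::model_config(),
                              test_fraction = 0.25, ngram_orders = 1:3) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$label_rule != "motif") {
    pep_abort("spec must use the motif label rule", "pep_config_error")
  }
  if (any(nchar(spec$motifs) < 3)) {
    pep_abort("motifs must have length >= 3", "pep_config_error")
  }
  data <- generate_peptides(spec)
  parts <- split_train_test(data, test_fraction, spec$seed + 1L)
  train <- parts$train
  test <- parts$test

  xtr_fp <- featurize(train, fp_config)
  xte_fp <- featurize(test, fp_config)
  fit_fp <- fit_peptide_model(xtr_fp, train[, "label", drop = FALSE],
                              config = model_config)
  met_fp <- evaluate_predictions(predict(fit_fp, xte_fp),
                                 test[, "label", drop = FALSE],
                                 fit_fp$task_types)

  xtr_ng <- aa_count_features(train, orders = ngram_orders)
  xte_ng <- aa_count_features(test, orders = ngram_orders)
  fit_ng <- fit_peptide_model(xtr_ng, train[, "label", drop = FALSE],
                              config = model_config)
  met_ng <- evaluate_predictions(predict(fit_ng, xte_ng),
                                 test[, "label", drop = FALSE],
                                 fit_ng$task_types)

  out <- dplyr::bind_rows(
    dplyr::mutate(met_fp, model = "fingerprint", .before = 1),
    dplyr::mutate(met_ng, model = "ngram_baseline", .before = 1))
  attr(out, "spec") <- spec
  class(out) <- c("pep_motif_test", "tbl_df", "tbl", "data.frame")
  out
}
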