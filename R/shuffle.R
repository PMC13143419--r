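# Sequence shuffling: the adversarial perturbation used to probe whether a
# model depends on residue order (long-range structure) or only on
# composition.

#' Randomly permute a fraction of residues within each sequence
#'
#' For each sequence of length L, `ceiling(ratio * L)` positions are chosen
#' uniformly without replacement and the letters at those positions are
#' replaced by a uniform random permutation of themselves (fixed points
#' allowed).  The residue multiset of every sequence is always preserved;
#' ratio 0 leaves sequences untouched.
#'
#' @param seqs Character vector of sequences.
#' @param ratio Shuffling ratio in `[0, 1]`.
#' @param seed Optional seed (RNG state is restored afterwards).
#' @return Character vector of shuffled sequences.
#' @export
#' @examples
#' shuffle_sequence("ACDE", ratio = 1, seed = 1) # an anagram of ACDE
shuffle_sequence <- function(seqs, ratio, seed = NULL) {
  if (ratio < 0 || ratio > 1) {
    pep_abort("ratio must be in [0, 1]", "pep_config_error")
  }
  seqs <- validate_sequences(seqs)
  if (ratio == 0) return(seqs)
  run <- function() {
    vapply(seqs, function(s) {
      ch <- strsplit(s, "")[[1]]
      L <- length(ch)
      k <- ceiling(ratio * L)
      pos <- sample.int(L, k)
      ch[pos] <- ch[pos][sample.int(k)]
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Shuffling-ratio control experiment
#'
#' For every shuffling ratio, shuffles the training sequences (with a fresh
#' per-ratio seed derived from the master seed), refeaturizes, retrains, and
#' evaluates on the untouched test set.  Optionally the perturbation can be
#' applied to the test side instead.
#'
#' @param train,test Data frames with `sequence` and label column(s); the
#'   sets should be disjoint.
#' @param ratios Numeric vector of shuffling ratios in `[0, 1]`.
#' @param fp_config An [fp_config()].
#' @param model_config A [model_config()].
#' @param seed Master seed for the per-ratio shuffle seeds.
#' @param label_cols Label column name(s); defaults to every column except
#'   `sequence` and `id`.
#' @param shuffle_test Shuffle test instead of training sequences (default
#'   `FALSE`).
#' @return A `pep_shuffle_experiment` tibble: one row per ratio, task and
#'   metric, with the per-cell seed recorded.
#' @export
run_shuffle_experiment <- function(train, test, ratios,
                                   fp_config = pepfp::fp_config(),
                                   model_config = pepfp::model_config(),
                                   seed = 1L, label_cols = NULL,
                                   shuffle_test = FALSE) {
  stopifnot(is.data.frame(train), is.data.frame(test), length(ratios) > 0)
  label_cols <- label_cols %||% setdiff(names(train), c("sequence", "id"))
  if (length(label_cols) == 0) {
    pep_abort("no label columns found", "pep_config_error")
  }
  cell_seeds <- seed_stream(seed, length(ratios))
  test_feat <- if (!shuffle_test) featurize(test, fp_config) else NULL
  rows <- lapply(seq_along(ratios), function(i) {
    r <- ratios[i]
    tr_seq <- train$sequence
    te_seq <- test$sequence
    if (shuffle_test) {
      te_seq <- shuffle_sequence(te_seq, r, seed = cell_seeds[i])
    } else {
      tr_seq <- shuffle_sequence(tr_seq, r, seed = cell_seeds[i])
    }
    xtr <- featurize(tr_seq, fp_config)
    xte <- if (shuffle_test) featurize(te_seq, fp_config) else test_feat
    fit <- fit_peptide_model(xtr, train[, label_cols, drop = FALSE],
                             config = model_config)
    scores <- predict(fit, xte)
    met <- evaluate_predictions(scores, test[, label_cols, drop = FALSE],
                                fit$task_types)
    dplyr::mutate(met, ratio = r, cell_seed = cell_seeds[i],
                  .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "fp_config") <- fp_config
  attr(out, "model_config") <- model_config
  attr(out, "seed") <- seed
  class(out) <- c("pep_shuffle_experiment", "tbl_df", "tbl", "data.frame")
  out
}
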