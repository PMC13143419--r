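# Small-n experiment harness checks; the full-scale qualitative runs live in
# the control-suite test.

small_dataset <- function(rule, n = 120, seed = 401, ...) {
  spec <- synthetic_spec(n = n, length_range = c(5, 15), label_rule = rule,
                         seed = seed, ...)
  generate_peptides(spec)
}

fast_model <- model_config(n_trees = 25, seed = 1)
tiny_fp <- fp_config(n_bits = 256)

test_that("a ratios = 0 grid equals the unshuffled pipeline exactly", {
  d <- small_dataset("composition_threshold")
  train <- d[1:90, ]
  test <- d[91:120, ]
  res <- run_shuffle_experiment(train, test, ratios = 0, fp_config = tiny_fp,
                                model_config = fast_model, seed = 5)
  fit <- fit_peptide_model(featurize(train, tiny_fp), train[, "label"],
                           config = fast_model)
  base <- evaluate_predictions(predict(fit, featurize(test, tiny_fp)),
                               test[, "label"], fit$task_types)
  expect_equal(res$value, base$value)
  expect_identical(unique(res$ratio), 0)
})

test_that("homopolymer datasets give a flat shuffling curve", {
  withr::with_seed(402, {
    letters <- sample(c("K", "A"), 80, replace = TRUE)
    seqs <- vapply(letters, function(l) {
      paste(rep(l, sample(4:12, 1)), collapse = "")
    }, character(1), USE.NAMES = FALSE)
    d <- tibble::tibble(sequence = seqs, label = as.integer(letters == "K"))
  })
  res <- run_shuffle_experiment(d[1:60, ], d[61:80, ], ratios = c(0, 0.5, 1),
                                fp_config = tiny_fp,
                                model_config = fast_model, seed = 6)
  by_metric <- split(res$value, res$metric)
  for (vals in by_metric) expect_equal(max(vals) - min(vals), 0)
})

test_that("the shuffle grid has one report row per cell and records seeds", {
  d <- small_dataset("composition_threshold")
  res <- run_shuffle_experiment(d[1:90, ], d[91:120, ],
                                ratios = c(0, 0.5, 1), fp_config = tiny_fp,
                                model_config = fast_model, seed = 7)
  expect_s3_class(res, "pep_shuffle_experiment")
  expect_identical(nrow(res), 3L * 4L) # 3 ratios x 4 binary metrics
  expect_identical(length(unique(res$cell_seed)), 3L)
  p <- ggplot2::autoplot(res)
  expect_s3_class(p, "ggplot")
})

test_that("the ablation reports all variants with count-minus-binary deltas", {
  d <- small_dataset("size_regression", n = 150, seed = 403)
  res <- count_vs_binary_ablation(d[1:110, ], d[111:150, ],
                                  families = "circular",
                                  fp_options = list(n_bits = 256),
                                  model_config = fast_model)
  expect_s3_class(res, "pep_ablation")
  expect_setequal(unique(res$variant), c("count", "binary", "binary_length"))
  expect_identical(unique(res$metric), "mae")
  deltas <- attr(res, "delta")
  expect_identical(names(deltas),
                   c("family", "task", "metric", "count", "binary", "delta"))
  expect_equal(deltas$delta, deltas$count - deltas$binary)
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})

test_that("degenerate labels surface per ablation cell without aborting", {
  d <- small_dataset("composition_threshold")
  d$label <- 1L
  res <- suppressWarnings(
    count_vs_binary_ablation(d[1:90, ], d[91:120, ], families = "circular",
                             fp_options = list(n_bits = 128),
                             model_config = fast_model))
  expect_true(all(grepl("degenerate", res$error)))
})

test_that("the motif stress test runs both models on the identical split", {
  spec <- synthetic_spec(n = 150, length_range = c(6, 15),
                         label_rule = "motif", motifs = c("KKK", "RRR"),
                         imbalance = 0.3, seed = 404)
  res <- motif_stress_test(spec, fp_config = tiny_fp,
                           model_config = fast_model)
  expect_s3_class(res, "pep_motif_test")
  expect_setequal(unique(res$model), c("fingerprint", "ngram_baseline"))
  expect_identical(sum(res$metric == "auroc"), 2L)
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})

test_that("single-letter motifs are rejected up front", {
  spec <- synthetic_spec(n = 50, label_rule = "motif", motifs = "K", seed = 1)
  expect_error(motif_stress_test(spec), class = "pep_config_error")
})
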