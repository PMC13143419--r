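#' Run the full synthetic control suite
#'
#' Runs the three qualitative control experiments on synthetic data, each
#' repeated over independently seeded replicates:
#'
#' * size regression (targets = summed monoisotopic residue masses): count
#'   versus binary versus binary-plus-length fingerprint variants (MAE);
#' * composition-threshold classification: test AUROC with untouched versus
#'   fully shuffled training sequences;
#' * charged-motif classification ("KKK"/"RRR"): fingerprint model versus a
#'   uni/bi/trigram sequence baseline (paired AUROC).
#'
#' @param master_seed Master seed; per-replicate seeds are derived with
#'   [seed_stream()].
#' @param n_train,n_test Training and test set sizes (defaults 2000/500).
#' @param n_seeds Number of replicates (default 5).
#' @param fp_config Fingerprint configuration (default circular/ECFP-style,
#'   radius 2, 2048 bits, count).
#' @param model_config Model configuration (default 500 trees, class
#'   weighting on).
#' @return A tibble with columns `experiment`, `replicate`, `seed`,
#'   `quantity`, `value`, one row per measured quantity per replicate.
#' @export
run_control_suite <- function(master_seed = 1L, n_train = 2000L,
                              n_test = 500L, n_seeds = 5L,
                              fp_config = pepfp::fp_config(),
                              model_config = pepfp::model_config()) {
  seeds <- seed_stream(master_seed, n_seeds)
  n_total <- n_train + n_test
  rows <- list()
  add <- function(experiment, replicate, seed, quantity, value) {
    rows[[length(rows) + 1]] <<- tibble(
      experiment = experiment, replicate = replicate, seed = seed,
      quantity = quantity, value = value)
  }
  for (i in seq_len(n_seeds)) {
    s <- seeds[i]

    # (a) count vs binary on the size-regression task
    spec_sz <- synthetic_spec(n = n_total, label_rule = "size_regression",
                              seed = s)
    d <- generate_peptides(spec_sz)
    parts <- split_train_test(d, n_test / n_total, s + 1L)
    abl <- count_vs_binary_ablation(parts$train, parts$test,
                                    families = fp_config$family,
                                    fp_options = list(n_bits = fp_config$n_bits),
                                    model_config = model_config)
    for (v in c("count", "binary", "binary_length")) {
      add("size_regression", i, s, paste0("mae_", v),
          abl$value[abl$variant == v & abl$metric == "mae"])
    }

    # (b) shuffling robustness on the composition task
    spec_cmp <- synthetic_spec(n = n_total,
                               label_rule = "composition_threshold", seed = s)
    dc <- generate_peptides(spec_cmp)
    pc <- split_train_test(dc, n_test / n_total, s + 2L)
    sh <- run_shuffle_experiment(pc$train, pc$test, ratios = c(0, 1),
                                 fp_config = fp_config,
                                 model_config = model_config, seed = s)
    au <- sh$value[sh$metric == "auroc"]
    add("composition_shuffle", i, s, "auroc_ratio0", au[1])
    add("composition_shuffle", i, s, "auroc_ratio1", au[2])
    add("composition_shuffle", i, s, "auroc_abs_delta", abs(au[2] - au[1]))

    # (c) charged-motif stress test
    spec_m <- synthetic_spec(n = n_total, label_rule = "motif",
                             motifs = c("KKK", "RRR"), imbalance = 0.3,
                             seed = s)
    mt <- motif_stress_test(spec_m, fp_config = fp_config,
                            model_config = model_config,
                            test_fraction = n_test / n_total)
    add("motif", i, s, "auroc_fingerprint",
        mt$value[mt$model == "fingerprint" & mt$metric == "auroc"])
    add("motif", i, s, "auroc_trigram",
        mt$value[mt$model == "ngram_baseline" & mt$metric == "auroc"])
  }
  dplyr::bind_rows(rows)
}

#' Summarize a control-suite run
#'
#' @param suite Output of [run_control_suite()].
#' @return One-row tibble with the headline quantities: median MAE per
#'   variant, mean absolute shuffling AUROC change, median motif AUROCs, and
#'   the fraction of replicates where the fingerprint model trails the
#'   trigram baseline.
#' @export
summarize_control_suite <- function(suite) {
  q <- function(qty) suite$value[suite$quantity == qty]
  tibble(
    mae_count = stats::median(q("mae_count")),
    mae_binary = stats::median(q("mae_binary")),
    mae_binary_length = stats::median(q("mae_binary_length")),
    shuffle_auroc_abs_delta = mean(q("auroc_abs_delta")),
    auroc_unshuffled = mean(q("auroc_ratio0")),
    motif_auroc_fingerprint = stats::median(q("auroc_fingerprint")),
    motif_auroc_trigram = stats::median(q("auroc_trigram")),
    motif_fp_below_trigram = mean(q("auroc_fingerprint") < q("auroc_trigram")),
    n_replicates = length(unique(suite$replicate)))
}
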