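test_that("class weights are inversely proportional to positive frequency", {
  expect_equal(class_weights(c(rep(0, 8), rep(1, 2))),
               c(w_pos = 4, w_neg = 1))
  expect_equal(class_weights(rep(c(0, 1), 5)), c(w_pos = 1, w_neg = 1))
  expect_error(class_weights(rep(1, 5)), class = "pep_degenerate_error")
  expect_error(class_weights(rep(0, 5)), class = "pep_degenerate_error")
  expect_error(class_weights(c(0, 1, 2)), class = "pep_config_error")
})

test_that("model config pins the boosted-tree defaults", {
  cfg <- model_config()
  expect_identical(cfg$n_trees, 500L)
  expect_true(cfg$class_weighting)
  expect_identical(unname(cfg$objective["binary"]), "log-loss")
  expect_identical(unname(cfg$objective["regression"]), "mae")
  expect_error(model_config(n_trees = 0), class = "pep_config_error")
})

toy_separable <- function(n = 20, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(0, 1), each = n / 2)
    x <- cbind(f1 = y * 2 + runif(n), f2 = runif(n))
    list(x = x, y = y)
  })
}

test_that("a separable toy problem is fit perfectly", {
  d <- toy_separable()
  fit <- fit_peptide_model(d$x, cbind(label = d$y),
                           config = model_config(n_trees = 50))
  s <- predict(fit, d$x)
  expect_equal(auroc(s$label, d$y), 1)
})

test_that("constant features give chance-level ranking", {
  withr::with_seed(2, {
    x <- matrix(1, nrow = 40, ncol = 3)
    y <- rep(c(0, 1), 20)
    fit <- fit_peptide_model(x, cbind(label = y),
                             config = model_config(n_trees = 20))
    s <- predict(fit, x)
    expect_equal(auroc(s$label, y), 0.5)
  })
})

test_that("multi-task bundles keep column order and isolate failures", {
  d <- toy_separable(n = 30)
  targets <- cbind(t1 = d$y, broken = rep(1, 30), t3 = rev(d$y))
  expect_warning(
    fit <- fit_peptide_model(d$x, targets,
                             config = model_config(n_trees = 20)),
    "broken")
  expect_identical(fit$tasks, c("t1", "broken", "t3"))
  expect_null(fit$models[["broken"]])
  td <- tidy(fit)
  expect_identical(td$trained, c(TRUE, FALSE, TRUE))
  s <- predict(fit, d$x)
  expect_identical(names(s), c("t1", "broken", "t3"))
  expect_true(all(is.na(s$broken)))
  expect_false(anyNA(s$t1))
  expect_identical(glance(fit)$n_trained, 2L)
  # an all-degenerate target set is a hard error
  expect_error(
    suppressWarnings(fit_peptide_model(d$x, cbind(z = rep(1, 30)))),
    class = "pep_degenerate_error")
})

test_that("fixed seeds and inputs reproduce identical predictions", {
  spec <- synthetic_spec(n = 60, length_range = c(5, 15),
                         label_rule = "composition_threshold", seed = 12)
  d <- generate_peptides(spec)
  f <- featurize(d, fp_config(n_bits = 256))
  cfg <- model_config(n_trees = 30, seed = 7)
  s1 <- predict(fit_peptide_model(f, d[, "label"], config = cfg), f)
  s2 <- predict(fit_peptide_model(f, d[, "label"], config = cfg), f)
  expect_identical(s1, s2)
})

test_that("class weighting does not reduce recall on imbalanced data", {
  # 5% positives; recall at threshold 0.5 with weights must not fall below
  # the unweighted recall, aggregated over 10 seeds
  recalls <- vapply(1:10, function(seed) {
    withr::with_seed(seed, {
      n <- 300
      y <- as.integer(runif(n) < 0.05)
      while (sum(y) < 3) y <- as.integer(runif(n) < 0.05)
      x <- cbind(f1 = y + rnorm(n, sd = 0.8), f2 = rnorm(n))
      xt <- cbind(f1 = y + rnorm(n, sd = 0.8), f2 = rnorm(n))
      fit_w <- fit_peptide_model(x, cbind(label = y),
                                 config = model_config(n_trees = 40,
                                                       seed = seed))
      fit_u <- fit_peptide_model(x, cbind(label = y),
                                 config = model_config(n_trees = 40,
                                                       class_weighting = FALSE,
                                                       seed = seed))
      rec <- function(fit) {
        s <- predict(fit, xt)$label
        tp <- sum(s >= 0.5 & y == 1)
        tp / sum(y == 1)
      }
      c(w = rec(fit_w), u = rec(fit_u))
    })
  }, numeric(2))
  expect_gte(mean(recalls["w", ]), mean(recalls["u", ]))
})

test_that("amino-acid n-gram counts follow the fixed alphabetical layout", {
  m <- aa_count_features("GGA")
  expect_identical(ncol(m), 420L)
  expect_equal(m[1, "G"], 2)
  expect_equal(m[1, "A"], 1)
  expect_equal(m[1, "GG"], 1)
  expect_equal(m[1, "GA"], 1)
  expect_equal(sum(m[1, nchar(colnames(m)) == 2]), 2) # two bigrams total

  m1 <- aa_count_features("A")
  expect_equal(sum(m1[1, nchar(colnames(m1)) == 1]), 1)
  expect_equal(sum(m1[1, nchar(colnames(m1)) == 2]), 0)

  # permutation keeps unigrams, generally changes bigrams
  ma <- aa_count_features("ACKW")
  mb <- aa_count_features("WKCA")
  uni <- nchar(colnames(ma)) == 1
  expect_equal(ma[1, uni], mb[1, uni])
  expect_false(all(ma[1, !uni] == mb[1, !uni]))

  m3 <- aa_count_features("KKKA", orders = 1:3)
  expect_identical(ncol(m3), 420L + 8000L)
  expect_equal(m3[1, "KKK"], 1)
})

test_that("binary_plus_length appends exactly one length column", {
  x <- matrix(0, nrow = 2, ncol = 8)
  out <- binary_plus_length(x, c("GG", "GGG"))
  expect_identical(dim(out), c(2L, 9L))
  expect_equal(unname(out[, "seq_length"]), c(2, 3))
  expect_error(binary_plus_length(out, c("GG", "GGG")),
               class = "pep_config_error") # no double augmentation
  empty <- matrix(0, nrow = 2, ncol = 0)
  out0 <- binary_plus_length(empty, c("GG", "GGG"))
  expect_identical(dim(out0), c(2L, 1L))
})
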