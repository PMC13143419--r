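test_that("spec validation enforces the generator invariants", {
  expect_error(synthetic_spec(length_range = c(2, 10)),
               class = "pep_config_error") # min length >= 3
  expect_error(synthetic_spec(label_rule = "motif", motifs = character(0)),
               class = "pep_config_error")
  expect_error(synthetic_spec(noise = 0.5), class = "pep_config_error")
  expect_error(synthetic_spec(noise = -0.1), class = "pep_config_error")
  expect_error(synthetic_spec(imbalance = 1.2), class = "pep_config_error")
  expect_error(synthetic_spec(label_rule = "size_regression",
                              imbalance = 0.3),
               class = "pep_config_error")
})

test_that("planted labels match a brute-force relabeling at zero noise", {
  spec_c <- synthetic_spec(n = 200, length_range = c(5, 20),
                           label_rule = "composition_threshold",
                           letters = c("K", "R"), cutoff = 0.15, seed = 31)
  d <- generate_peptides(spec_c)
  frac <- vapply(strsplit(d$sequence, ""),
                 function(ch) mean(ch %in% c("K", "R")), numeric(1))
  expect_identical(d$label, as.integer(frac > 0.15))

  spec_m <- synthetic_spec(n = 200, length_range = c(5, 20),
                           label_rule = "motif", motifs = c("KKK", "RRR"),
                           imbalance = 0.3, seed = 32)
  dm <- generate_peptides(spec_m)
  expect_identical(dm$label,
                   as.integer(grepl("KKK", dm$sequence, fixed = TRUE) |
                              grepl("RRR", dm$sequence, fixed = TRUE)))

  spec_s <- synthetic_spec(n = 50, label_rule = "size_regression", seed = 33)
  ds <- generate_peptides(spec_s)
  masses <- vapply(strsplit(ds$sequence, ""),
                   function(ch) sum(RESIDUE_MASSES[ch]), numeric(1))
  expect_equal(ds$label, masses)
})

test_that("explicit motif examples follow the substring definition", {
  spec <- synthetic_spec(label_rule = "motif", motifs = c("KKK", "RRR"))
  expect_identical(apply_label_rule(spec, c("AKKKA", "AKAKAKA", "RRRW")),
                   c(1L, 0L, 1L))
})

test_that("a fixed spec and seed generate identical datasets", {
  spec <- synthetic_spec(n = 100, label_rule = "motif", imbalance = 0.3,
                         seed = 77)
  expect_identical(generate_peptides(spec), generate_peptides(spec))
})

test_that("rejection sampling hits the target imbalance or errors", {
  spec <- synthetic_spec(n = 200, label_rule = "motif", imbalance = 0.25,
                         seed = 5)
  d <- generate_peptides(spec)
  expect_equal(mean(d$label), 0.25)
  # a motif longer than any sequence can never be positive
  bad <- synthetic_spec(n = 20, length_range = c(3, 5), label_rule = "motif",
                        motifs = "WWWWWWWWWW", imbalance = 0.5, seed = 6)
  expect_error(generate_peptides(bad), "unreachable",
               class = "pep_config_error")
})

test_that("label noise flips approximately the stated fraction", {
  spec0 <- synthetic_spec(n = 2000, length_range = c(5, 15),
                          label_rule = "composition_threshold", seed = 55)
  spec1 <- synthetic_spec(n = 2000, length_range = c(5, 15),
                          label_rule = "composition_threshold", noise = 0.2,
                          seed = 55)
  d0 <- generate_peptides(spec0)
  d1 <- generate_peptides(spec1)
  expect_identical(d0$sequence, d1$sequence)
  flip_rate <- mean(d0$label != d1$label)
  expect_gt(flip_rate, 0.15)
  expect_lt(flip_rate, 0.25)
})

test_that("shuffling preserves the residue multiset at every ratio", {
  sort_chars <- function(s) paste(sort(strsplit(s, "")[[1]]), collapse = "")
  seqs <- random_peptides(20, max_len = 30, seed = 8, min_len = 3)
  for (ratio in c(0.25, 0.5, 1)) {
    out <- shuffle_sequence(seqs, ratio, seed = 9)
    expect_identical(vapply(out, sort_chars, character(1), USE.NAMES = FALSE),
                     vapply(seqs, sort_chars, character(1), USE.NAMES = FALSE))
  }
})

test_that("shuffle edge cases: identity at ratio 0, anagram at ratio 1", {
  expect_identical(shuffle_sequence("ACDEFG", 0), "ACDEFG")
  expect_identical(shuffle_sequence("KKKKK", 1, seed = 3), "KKKKK")
  out <- shuffle_sequence("ACDE", 1, seed = 4)
  expect_identical(paste(sort(strsplit(out, "")[[1]]), collapse = ""), "ACDE")
  expect_error(shuffle_sequence("ACDE", 1.5), class = "pep_config_error")
})

test_that("seed streams are deterministic and well spread", {
  s1 <- seed_stream(42, 5)
  s2 <- seed_stream(42, 5)
  expect_identical(s1, s2)
  expect_identical(anyDuplicated(s1), 0L)
  expect_true(all(s1 >= 0 & s1 < 2^31))
  expect_false(identical(seed_stream(43, 5), s1))
})
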