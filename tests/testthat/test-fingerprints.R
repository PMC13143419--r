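test_that("atom invariants depend only on the local tuple", {
  g4 <- build_peptide_graph("GGGG")
  inv <- atom_invariants(g4)
  ca <- which(g4$atoms$name == "CA")
  interior_ca <- ca[2:3] # both flanked by amide N and carbonyl C
  expect_identical(inv[interior_ca[1]], inv[interior_ca[2]])

  g3 <- build_peptide_graph("GGG")
  inv3 <- atom_invariants(g3)
  n_atoms <- which(g3$atoms$name == "N")
  # N-terminal amine (degree 1, 2 H) vs interior amide N (degree 2, 1 H)
  expect_false(inv3[n_atoms[1]] == inv3[n_atoms[2]])
  expect_identical(inv3[n_atoms[2]], inv3[n_atoms[3]])

  lone <- make_graph("C", 4L, integer(0), integer(0), character(0))
  expect_length(atom_invariants(lone), 1)
})

test_that("radius-0 circular counts one instance per heavy atom", {
  for (s in c("G", "GG", "WHPK")) {
    g <- build_peptide_graph(s)
    expect_identical(fp_total(circular_fingerprint(g, radius = 0)),
                     nrow(g$atoms))
  }
  expect_identical(fp_total(circular_fingerprint(build_peptide_graph("GG"),
                                                 radius = 0)), 9L)
})

test_that("larger-radius environments on a single atom deduplicate to one", {
  lone <- make_graph("C", 4L, integer(0), integer(0), character(0))
  fp <- circular_fingerprint(lone, radius = 2)
  expect_identical(nrow(fp$counts), 1L)
  expect_identical(fp_total(fp), 1L)
})

test_that("circular fingerprints are invariant under atom relabeling", {
  g <- build_peptide_graph("ACK")
  perm <- withr::with_seed(7, sample(nrow(g$atoms)))
  gp <- permute_graph(g, perm)
  expect_same_counts(fp_counts(circular_fingerprint(g, 2)),
                     fp_counts(circular_fingerprint(gp, 2)))
  expect_same_counts(fp_counts(torsion_fingerprint(g, 4)),
                     fp_counts(torsion_fingerprint(gp, 4)))
  expect_same_counts(fp_counts(all_subgraph_fingerprint(g, 5)),
                     fp_counts(all_subgraph_fingerprint(gp, 5)))
})

test_that("torsion paths of GG match the closed-form tree count", {
  # on a tree, 4-atom paths = sum over middle edges of (deg-1)(deg-1) = 7
  fp <- torsion_fingerprint(build_peptide_graph("GG"), path_length = 4)
  expect_identical(fp_total(fp), 7L)
})

test_that("short chains admit no long paths", {
  chain3 <- make_graph(c("C", "C", "C"), c(3L, 2L, 3L), 1:2, 2:3,
                       rep("single", 2))
  fp <- torsion_fingerprint(chain3, path_length = 4)
  expect_identical(nrow(fp$counts), 0L)
  expect_identical(fp_total(fp), 0L)
})

test_that("palindromic paths hash identically in both orientations", {
  # N-C-C-N chain: type sequence is its own reverse, so the path contributes
  # a single key; and the two orientations of an asymmetric chain agree
  sym <- make_graph(c("N", "C", "C", "N"), c(2L, 2L, 2L, 2L), 1:3, 2:4,
                    rep("single", 3))
  fp <- torsion_fingerprint(sym, path_length = 4)
  expect_identical(nrow(fp$counts), 1L)
  expect_identical(fp_total(fp), 1L)
})

test_that("subgraph counts on micro fixtures match closed forms", {
  two <- make_graph(c("C", "C"), c(3L, 3L), 1L, 2L, "single")
  expect_identical(fp_total(all_subgraph_fingerprint(two, 7)), 1L)
  # 6-cycle: 6 paths of each length 1..5 plus the full ring = 31
  expect_identical(fp_total(all_subgraph_fingerprint(make_benzene(), 7)), 31L)
  # and the enumeration cap degrades to a classed size error
  expect_error(all_subgraph_fingerprint(build_peptide_graph("WW"), 7, cap = 10),
               class = "pep_size_error")
})

test_that("folding follows modulo indexing and conserves counts", {
  raw <- structure(list(
    counts = tibble::tibble(
      key = c(sprintf("%016x", 3), sprintf("%016x", 11)),
      count = c(2L, 1L)),
    family = "circular", params = list(radius = 2L), variant = "count",
    n_atoms = 2L), class = "pep_fingerprint")
  v <- fold_fingerprint(raw, n_bits = 8)
  expect_identical(as.integer(v), c(0L, 0L, 0L, 3L, 0L, 0L, 0L, 0L))
  b <- fold_fingerprint(raw, n_bits = 8, variant = "binary")
  expect_identical(as.integer(b), c(0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L))
  for (s in c("GG", "WHK")) {
    fp <- circular_fingerprint(build_peptide_graph(s), 2)
    for (nb in c(7L, 64L, 2048L)) {
      expect_identical(sum(fold_fingerprint(fp, nb)), fp_total(fp))
    }
  }
})

test_that("featurize preserves row order, totals and determinism", {
  cfg <- fp_config(n_bits = 2048)
  f <- featurize(c("G", "GG"), cfg)
  expect_identical(dim(f), c(2L, 2048L))
  raw_totals <- vapply(c("G", "GG"), function(s) {
    fp_total(circular_fingerprint(build_peptide_graph(s), 2))
  }, integer(1))
  expect_equal(unname(Matrix::rowSums(f$matrix)), unname(raw_totals))

  f1 <- featurize("AAAA", cfg)
  f2 <- featurize("AAAA", cfg)
  expect_identical(as.matrix(f1$matrix), as.matrix(f2$matrix))

  f0 <- featurize(character(0), cfg)
  expect_identical(dim(f0), c(0L, 2048L))
})

test_that("featurization errors name the offending record", {
  expect_error(featurize(tibble::tibble(id = c("ok", "bad"),
                                        sequence = c("GG", "GXG"))),
               "X", class = "pep_chem_error")
})

test_that("config defaults and round-trips pin the published sizes", {
  cfg <- fp_config()
  expect_identical(cfg$family, "circular")
  expect_identical(cfg$radius, 2L)      # diameter 4
  expect_identical(cfg$path_length, 4L)
  expect_identical(cfg$max_bonds, 7L)
  expect_identical(cfg$n_bits, 2048L)
  expect_identical(cfg$variant, "count")
  expect_identical(fp_tuning_grid("circular"), 2:4)
  expect_identical(fp_tuning_grid("torsion"), 4:6)
  expect_identical(fp_tuning_grid("all_subgraph"), 7:9)
  expect_error(fp_config(radius = -1), class = "pep_config_error")
  expect_error(fp_config(max_bonds = 12), class = "pep_config_error")
})
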