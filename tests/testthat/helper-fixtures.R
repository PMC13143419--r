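# Fixtures and small utilities shared across the suite.  All fixtures are
# built in code.

# A bare molecular graph from explicit atom/bond tables (for non-peptide
# fixtures such as the benzene ring).
make_graph <- function(element, n_H, bonds_from, bonds_to, order,
                       aromatic = FALSE, label = "fixture") {
  n <- length(element)
  aromatic <- rep_len(aromatic, n)
  bonds <- tibble::tibble(from = bonds_from, to = bonds_to, order = order)
  in_ring <- rep(FALSE, n)
  if (nrow(bonds) > 0) {
    ig <- igraph::graph_from_data_frame(bonds[, 1:2], directed = FALSE,
                                        vertices = data.frame(name = 1:n))
    ring_edges <- setdiff(seq_len(nrow(bonds)),
                          as.integer(igraph::bridges(ig)))
    in_ring[unique(c(bonds$from[ring_edges], bonds$to[ring_edges]))] <- TRUE
  }
  atoms <- tibble::tibble(
    residue = 1L, name = paste0(element, seq_len(n)), element = element,
    formal_charge = 0L, n_implicit_H = as.integer(n_H), aromatic = aromatic,
    in_ring = in_ring)
  g <- structure(list(atoms = atoms, bonds = bonds, sequence = label,
                      id = NULL), class = "pep_graph")
  g$atoms$pi_electrons <- graph_pi(g)
  g
}

graph_pi <- function(g) {
  ordv <- c(single = 1, double = 2, aromatic = 1.5)[g$bonds$order]
  n <- nrow(g$atoms)
  val <- numeric(n)
  deg <- integer(n)
  for (e in seq_len(nrow(g$bonds))) {
    for (v in c(g$bonds$from[e], g$bonds$to[e])) {
      val[v] <- val[v] + ordv[e]
      deg[v] <- deg[v] + 1L
    }
  }
  as.integer(pmax(0, round(val) - deg))
}

make_benzene <- function() {
  make_graph(rep("C", 6), rep(1L, 6), 1:6, c(2:6, 1L), rep("aromatic", 6),
             aromatic = TRUE, label = "benzene")
}

# random canonical peptide sequences under a local seed
random_peptides <- function(n, max_len, seed, min_len = 1) {
  withr::with_seed(seed, {
    replicate(n, paste(sample(pepfp::AA_ALPHABET,
                              sample(min_len:max_len, 1), replace = TRUE),
                       collapse = ""))
  })
}

# apply a random atom relabeling to a pep_graph
permute_graph <- function(g, perm) {
  inv <- order(perm)
  atoms <- g$atoms[perm, , drop = FALSE]
  bonds <- g$bonds
  bonds$from <- inv[bonds$from]
  bonds$to <- inv[bonds$to]
  structure(list(atoms = atoms, bonds = bonds, sequence = g$sequence,
                 id = g$id), class = "pep_graph")
}

# disjoint union of two pep_graphs
union_graph <- function(g1, g2) {
  n1 <- nrow(g1$atoms)
  bonds2 <- g2$bonds
  bonds2$from <- bonds2$from + n1
  bonds2$to <- bonds2$to + n1
  structure(list(atoms = dplyr::bind_rows(g1$atoms, g2$atoms),
                 bonds = dplyr::bind_rows(g1$bonds, bonds2),
                 sequence = paste0(g1$sequence, "+", g2$sequence), id = NULL),
            class = "pep_graph")
}

# compare two keyed count tables (tibbles with key/count) exactly
expect_same_counts <- function(a, b) {
  a <- a[order(a$key), c("key", "count")]
  b <- b[order(b$key), c("key", "count")]
  expect_equal(a$key, b$key)
  expect_equal(as.integer(a$count), as.integer(b$count))
}

fp_counts <- function(fp) fp$counts

# keywise sum of two raw count tables
sum_counts <- function(a, b) {
  out <- dplyr::summarise(dplyr::group_by(dplyr::bind_rows(a, b), key),
                          count = sum(count), .groups = "drop")
  out[order(out$key), ]
}
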