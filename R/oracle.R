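# Brute-force substructure enumeration, used as an independent oracle for the
# hashed fingerprints.  Code paths are deliberately separate from the
# fingerprint implementations: circular identifiers are recomputed by a
# memoized top-down recursion (the fingerprints use an iterative loop in C++),
# torsion paths come from igraph's simple-path enumeration, and subgraphs from
# a breadth-first closure over edge subsets with an explicit visited set.

#' Exhaustively enumerate substructure instances of a graph
#'
#' Non-hashed, brute-force enumeration of the substructure instances that the
#' corresponding hashed fingerprint retains: circular atom environments (with
#' bond-set deduplication), simple linear paths, or connected edge-induced
#' subgraphs.  Instance multiset sizes must match the corresponding
#' fingerprint totals, which is what the oracle-equivalence tests assert.
#'
#' @param graph A `pep_graph` (intended for small graphs).
#' @param mode `"circular_envs"`, `"paths"` or `"subgraphs"`.
#' @param size Radius (circular), path length in atoms (paths) or maximum
#'   bond count (subgraphs).
#' @param cap Abort with an oracle-scope error beyond this many instances.
#' @return A tibble with one row per substructure class: `key` (64-bit hex
#'   identifier comparable with the fingerprint keys) and `count` (number of
#'   instances); total instances = `sum(count)`.
#' @export
enumerate_substructures <- function(graph,
                                    mode = c("circular_envs", "paths",
                                             "subgraphs"),
                                    size, cap = 1e7) {
  stopifnot(inherits(graph, "pep_graph"))
  mode <- match.arg(mode)
  switch(mode,
    circular_envs = oracle_circular(graph, size),
    paths = oracle_paths(graph, size),
    subgraphs = oracle_subgraphs(graph, size, cap))
}

# -- circular environments ---------------------------------------------------

oracle_circular <- function(graph, radius) {
  stopifnot(radius >= 0)
  a <- graph$atoms
  b <- graph$bonds
  n <- nrow(a)
  code <- bond_order_code(b$order)
  # invariant strings assembled independently in R
  val10 <- integer(n)
  deg <- integer(n)
  ordv <- c(single = 10L, double = 20L, aromatic = 15L)[b$order]
  for (e in seq_len(nrow(b))) {
    for (v in c(b$from[e], b$to[e])) {
      deg[v] <- deg[v] + 1L
      val10[v] <- val10[v] + ordv[e]
    }
  }
  inv <- fnv1a64_str(sprintf("INV|%d|%d|%d|%d|%d|%d",
                             element_z(a$element), deg, a$n_implicit_H,
                             a$formal_charge, as.integer(a$in_ring),
                             val10 + 10L * a$n_implicit_H))

  nbrs <- lapply(seq_len(n), function(v) {
    sel <- b$from == v | b$to == v
    list(atom = ifelse(b$from[sel] == v, b$to[sel], b$from[sel]),
         code = code[sel])
  })

  memo <- matrix(NA_character_, nrow = n, ncol = radius + 1L)
  oid <- function(v, r) {
    if (!is.na(memo[v, r + 1L])) return(memo[v, r + 1L])
    id <- if (r == 0) {
      inv[v]
    } else {
      nb <- nbrs[[v]]
      nid <- vapply(nb$atom, oid, character(1), r = r - 1L)
      ord <- order(nb$code, nid)
      fnv1a64_str(paste0("ECFP|", r, "|", oid(v, r - 1L),
                         paste0("|", nb$code[ord], ":", nid[ord],
                                collapse = "")))
    }
    memo[v, r + 1L] <<- id
    id
  }

  dmat <- igraph::distances(graph_to_igraph(graph))
  insts <- list()
  k <- 0L
  for (r in 0:radius) {
    for (v in seq_len(n)) {
      bset <- if (r == 0) integer(0) else {
        which(pmin(dmat[b$from, v], dmat[b$to, v]) <= r - 1)
      }
      k <- k + 1L
      insts[[k]] <- list(r = r, id = oid(v, r), atom = v, bset = bset)
    }
  }
  rr <- vapply(insts, `[[`, numeric(1), "r")
  ids <- vapply(insts, `[[`, character(1), "id")
  ord <- order(rr, ids)
  seen <- character(0)
  kept <- character(0)
  for (i in ord) {
    inst <- insts[[i]]
    if (inst$r == 0) {
      kept <- c(kept, inst$id)
    } else if (length(inst$bset) == 0) {
      next
    } else {
      bkey <- paste(inst$bset, collapse = ",")
      if (!bkey %in% seen) {
        seen <- c(seen, bkey)
        kept <- c(kept, inst$id)
      }
    }
  }
  tab <- table(kept)
  tibble(key = names(tab), count = as.integer(tab))
}

# -- linear paths ------------------------------------------------------------

oracle_paths <- function(graph, path_length) {
  stopifnot(path_length >= 2)
  a <- graph$atoms
  b <- graph$bonds
  deg <- tabulate(c(b$from, b$to), nbins = nrow(a))
  z <- element_z(a$element)
  pi_e <- a$pi_electrons
  ig <- graph_to_igraph(graph)
  paths <- list()
  for (v in seq_len(nrow(a))) {
    ps <- igraph::all_simple_paths(ig, from = v, cutoff = path_length - 1)
    ps <- Filter(function(p) length(p) == path_length, ps)
    # keep each undirected path once
    ps <- Filter(function(p) as.integer(p[1]) < as.integer(p[length(p)]), ps)
    paths <- c(paths, lapply(ps, as.integer))
  }
  if (length(paths) == 0) {
    return(tibble(key = character(0), count = integer(0)))
  }
  type_str <- function(p) {
    d <- deg[p]
    d[c(1, length(p))] <- d[c(1, length(p))] - 1L
    fwd <- sprintf("%d,%d,%d", z[p], pi_e[p], d)
    # pick the lexicographically smaller orientation of the numeric triple
    # sequence; zero-padded strings make string order match numeric order
    pad <- sprintf("%03d.%03d.%03d", z[p], pi_e[p], d)
    use_rev <- paste(rev(pad), collapse = "#") < paste(pad, collapse = "#")
    paste0("TT|", paste(if (use_rev) rev(fwd) else fwd, collapse = "|"))
  }
  keys <- fnv1a64_str(vapply(paths, type_str, character(1)))
  tab <- table(keys)
  tibble(key = names(tab), count = as.integer(tab))
}

# -- connected subgraphs -----------------------------------------------------

oracle_subgraphs <- function(graph, max_bonds, cap) {
  if (nrow(graph$bonds) > 256) {
    pep_abort("oracle-scope error: graph has more than 256 bonds",
              "pep_size_error")
  }
  df <- tryCatch(
    cpp_subgraph_oracle(graph_atom_matrix(graph), graph_bond_matrix(graph),
                        as.integer(max_bonds), cap),
    error = function(e) {
      if (grepl("oracle-scope", conditionMessage(e))) {
        pep_abort(conditionMessage(e), "pep_size_error", parent = e)
      }
      stop(e)
    })
  as_tibble(df)
}
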