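#' Build the atom-level molecular graph of a peptide
#'
#' Deterministically constructs the hydrogen-suppressed heavy-atom graph of a
#' linear peptide from its one-letter sequence, by chaining embedded residue
#' templates N-to-C with single peptide bonds.  The N-terminus is modeled as a
#' free amine by incrementing the backbone nitrogen's implicit-hydrogen count;
#' the C-terminus gains one hydroxyl oxygen (appended as the last atom), so
#' the heavy-atom count is always the sum of the template sizes plus one.
#' Atom ordering is residue-major with template-internal order, making the
#' serialization reproducible.  All atoms are neutral, cysteines stay reduced
#' (no disulfide bridges), and stereochemistry is ignored.
#'
#' @param sequence A single peptide sequence (uppercase canonical one-letter
#'   codes).
#' @param id Optional identifier stored with the graph.
#' @return A `pep_graph`: list with `atoms` (tibble with columns `residue`,
#'   `name`, `element`, `formal_charge`, `n_implicit_H`, `aromatic`,
#'   `in_ring`, `pi_electrons`), `bonds` (tibble `from`, `to`, `order`), and
#'   the source `sequence`.
#' @export
#' @examples
#' g <- build_peptide_graph("GG")
#' nrow(g$atoms) # 9 heavy atoms
#' nrow(g$bonds) # 8 bonds
build_peptide_graph <- function(sequence, id = NULL) {
  if (length(sequence) != 1 || !is.character(sequence) || is.na(sequence)) {
    pep_abort("sequence must be a single string", "pep_config_error")
  }
  if (!nzchar(sequence)) {
    pep_abort("empty sequence", "pep_input_error")
  }
  sequence <- validate_sequences(sequence)
  letters <- strsplit(sequence, "")[[1]]
  tpls <- lapply(letters, tpl_vectors)
  sizes <- vapply(tpls, function(t) t$n_atoms, integer(1))
  offsets <- c(0L, cumsum(sizes))[seq_along(letters)]

  name <- c(unlist(lapply(tpls, `[[`, "name"), use.names = FALSE), "OXT")
  element <- c(unlist(lapply(tpls, `[[`, "element"), use.names = FALSE), "O")
  n_h <- c(unlist(lapply(tpls, `[[`, "nH"), use.names = FALSE), 1L)
  aromatic <- c(unlist(lapply(tpls, `[[`, "aromatic"), use.names = FALSE),
                FALSE)
  residue <- c(rep(seq_along(letters), sizes), length(letters))
  # free amine at the N-terminus
  n_h[tpls[[1]]$n_attach] <- n_h[tpls[[1]]$n_attach] + 1L

  c_attach <- vapply(tpls, function(t) t$c_attach, integer(1)) + offsets
  n_attach <- vapply(tpls, function(t) t$n_attach, integer(1)) + offsets
  n_atoms <- sum(sizes) + 1L
  # template-internal bonds, peptide bonds, C-terminal hydroxyl oxygen
  from <- c(unlist(mapply(`+`, lapply(tpls, `[[`, "bond_from"), offsets,
                          SIMPLIFY = FALSE), use.names = FALSE),
            c_attach[-length(letters)][seq_len(length(letters) - 1)],
            c_attach[length(letters)])
  to <- c(unlist(mapply(`+`, lapply(tpls, `[[`, "bond_to"), offsets,
                        SIMPLIFY = FALSE), use.names = FALSE),
          n_attach[-1][seq_len(length(letters) - 1)],
          n_atoms)
  order <- c(unlist(lapply(tpls, `[[`, "bond_order"), use.names = FALSE),
             rep("single", length(letters)))

  bond_mat <- cbind(u = from - 1L, v = to - 1L, code = bond_order_code(order))
  # ring membership is recomputed from the assembled graph, not trusted from
  # the templates
  in_ring <- as.logical(cpp_ring_atoms(n_atoms, bond_mat))
  atom_mat <- cbind(Z = element_z(element), nH = n_h, chg = 0L,
                    arom = as.integer(aromatic), ring = as.integer(in_ring))
  atoms <- tibble(residue = residue, name = name, element = element,
                  formal_charge = 0L, n_implicit_H = n_h,
                  aromatic = aromatic, in_ring = in_ring,
                  pi_electrons = as.integer(cpp_pi_electrons(atom_mat,
                                                             bond_mat)))
  bonds <- tibble(from = from, to = to, order = order)
  structure(list(atoms = atoms, bonds = bonds, sequence = sequence, id = id),
            class = "pep_graph")
}

# plain-vector template cache used by the graph assembler
.tpl_vec_cache <- new.env(parent = emptyenv())
tpl_vectors <- function(letter) {
  v <- .tpl_vec_cache[[letter]]
  if (is.null(v)) {
    tpl <- residue_template(letter)
    v <- list(n_atoms = nrow(tpl$atoms),
              name = tpl$atoms$name,
              element = tpl$atoms$element,
              nH = tpl$atoms$n_implicit_H,
              aromatic = tpl$atoms$aromatic,
              bond_from = tpl$bonds$from,
              bond_to = tpl$bonds$to,
              bond_order = tpl$bonds$order,
              n_attach = tpl$n_attach,
              c_attach = tpl$c_attach)
    .tpl_vec_cache[[letter]] <- v
  }
  v
}

# integer matrices handed to the C++ core
graph_atom_matrix <- function(graph) {
  a <- graph$atoms
  cbind(Z = element_z(a$element),
        nH = a$n_implicit_H,
        chg = a$formal_charge,
        arom = as.integer(a$aromatic),
        ring = as.integer(a$in_ring))
}

graph_bond_matrix <- function(graph) {
  b <- graph$bonds
  m <- cbind(u = b$from - 1L, v = b$to - 1L, code = bond_order_code(b$order))
  if (nrow(b) == 0) m <- matrix(integer(0), ncol = 3) # single-atom graphs
  m
}

#' @export
print.pep_graph <- function(x, ...) {
  cat(sprintf("<pep_graph \"%s\": %d heavy atoms, %d bonds>\n",
              x$sequence, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

#' @export
as_tibble.pep_graph <- function(x, ...) x$atoms

# igraph view of a pep_graph (used by oracles)
graph_to_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$bonds[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(graph$atoms))))
}

#' Serialize peptide graphs as JSON lines
#'
#' One JSON object per line with `sequence`, an `atoms` array and a `bonds`
#' array; a plain-text dialect used for fixtures and interchange.
#'
#' @param graphs A `pep_graph` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphs_jsonl <- function(graphs, path) {
  if (inherits(graphs, "pep_graph")) graphs <- list(graphs)
  lines <- vapply(graphs, function(g) {
    jsonlite::toJSON(list(
      sequence = g$sequence,
      id = g$id,
      atoms = g$atoms,
      bonds = g$bonds
    ), dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read peptide graphs from JSON lines
#'
#' @param path File written by [write_graphs_jsonl()].
#' @return List of `pep_graph` objects.
#' @export
read_graphs_jsonl <- function(path) {
  if (!file.exists(path)) {
    pep_abort(sprintf("file not found: %s", path), "pep_io_error")
  }
  lapply(readLines(path), function(line) {
    obj <- jsonlite::fromJSON(line)
    structure(list(atoms = as_tibble(obj$atoms),
                   bonds = as_tibble(obj$bonds),
                   sequence = obj$sequence,
                   id = obj$id),
              class = "pep_graph")
  })
}
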