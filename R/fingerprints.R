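# Hashed molecular fingerprints.
#
# Substructure identifiers are seedless 64-bit FNV-1a hashes of canonical
# ASCII strings, so they are stable across runs and platforms.  The byte
# layouts ("hash dialect") are:
#
#   atom invariant   "INV|Z|deg|nH|chg|ring|val10"
#                    val10 = 10 * (heavy bond-order sum + nH), aromatic = 1.5
#   circular update  "ECFP|r|<id(a,r-1)>|code:<id(n1,r-1)>|..."
#                    neighbor pairs sorted by (bond code, identifier)
#   torsion path     "TT|Z,pi,deg|..." over the lexicographically smaller of
#                    the forward/reverse type sequence; terminal degrees
#                    decremented by 1
#   subgraph         "SG|..." canonical column serialization minimized over
#                    vertex orderings (atom label Z/charge/aromatic, bond
#                    order codes)
#
# Bond order codes: single = 1, double = 2, aromatic = 4 (aromatic bonds hash
# as their own code, no Kekule assignment).

new_raw_fp <- function(df, family, params, variant, n_atoms) {
  tbl <- as_tibble(df)
  structure(list(counts = tbl, family = family, params = params,
                 variant = variant, n_atoms = n_atoms),
            class = "pep_fingerprint")
}

#' @export
print.pep_fingerprint <- function(x, ...) {
  cat(sprintf("<pep_fingerprint %s: %d keys, %d instances (%s variant)>\n",
              x$family, nrow(x$counts), sum(x$counts$count), x$variant))
  invisible(x)
}

#' @export
as_tibble.pep_fingerprint <- function(x, ...) x$counts

#' Total number of substructure instances in a raw fingerprint
#' @param fp A `pep_fingerprint`.
#' @return Integer total count.
#' @export
fp_total <- function(fp) {
  stopifnot(inherits(fp, "pep_fingerprint"))
  sum(fp$counts$count)
}

#' Initial per-atom identifiers
#'
#' Hashes each atom's local tuple (atomic number, heavy-neighbor count, total
#' hydrogen count, formal charge, ring flag, total bond-order valence) to its
#' initial 64-bit identifier; identical local tuples give identical
#' identifiers.  These are the radius-0 identifiers of the circular
#' fingerprint.
#'
#' @param graph A `pep_graph`.
#' @return Character vector of 16-hex-digit identifiers, one per atom.
#' @export
atom_invariants <- function(graph) {
  stopifnot(inherits(graph, "pep_graph"))
  cpp_atom_invariants(graph_atom_matrix(graph), graph_bond_matrix(graph))
}

#' Circular (Morgan/ECFP-style) fingerprint
#'
#' For each atom and each radius r in 0..`radius`, iteratively hashes the
#' atom's previous identifier together with its neighbors' identifiers and
#' bond orders (the Morgan algorithm).  Environments whose bond sets duplicate
#' an already-kept environment are removed, keeping the smallest radius and
#' breaking ties by smaller identifier; each surviving (atom, radius)
#' instance contributes one count.
#'
#' @param graph A `pep_graph`.
#' @param radius Maximum radius (default 2, i.e. diameter 4).
#' @param variant `"count"` or `"binary"` (recorded; applied at folding).
#' @return A `pep_fingerprint` with a `counts` tibble (`key`, `count`).
#' @export
#' @examples
#' fp <- circular_fingerprint(build_peptide_graph("GG"), radius = 0)
#' fp_total(fp) # one instance per heavy atom at radius 0
circular_fingerprint <- function(graph, radius = 2L,
                                 variant = c("count", "binary")) {
  stopifnot(inherits(graph, "pep_graph"))
  variant <- match.arg(variant)
  if (radius < 0) pep_abort("radius must be >= 0", "pep_config_error")
  df <- cpp_morgan(graph_atom_matrix(graph), graph_bond_matrix(graph),
                   as.integer(radius))
  new_raw_fp(df, "circular", list(radius = as.integer(radius)), variant,
             nrow(graph$atoms))
}

#' Topological torsion fingerprint
#'
#' Enumerates all simple paths of exactly `path_length` atoms (each undirected
#' path once).  Atoms are typed by (atomic number, pi-electron count, heavy
#' degree), with the two terminal degrees decremented by one to exclude the
#' path-internal bond; the path key hashes the lexicographically smaller of
#' the forward/reverse type sequence.
#'
#' @inheritParams circular_fingerprint
#' @param path_length Path length in atoms (default 4).
#' @return A `pep_fingerprint`.
#' @export
torsion_fingerprint <- function(graph, path_length = 4L,
                                variant = c("count", "binary")) {
  stopifnot(inherits(graph, "pep_graph"))
  variant <- match.arg(variant)
  if (path_length < 2) pep_abort("path_length must be >= 2", "pep_config_error")
  df <- cpp_torsion(graph_atom_matrix(graph), graph_bond_matrix(graph),
                    as.integer(path_length))
  new_raw_fp(df, "torsion", list(path_length = as.integer(path_length)),
             variant, nrow(graph$atoms))
}

#' All-connected-subgraph fingerprint
#'
#' Enumerates every connected edge-induced subgraph with 1..`max_bonds` bonds
#' exactly once (branched and cyclic shapes included) and keys each by a
#' canonical form obtained by brute-force minimization over vertex orderings
#' of its labeled edge list.
#'
#' @inheritParams circular_fingerprint
#' @param max_bonds Bond-count limit (1..9; default 7).
#' @param cap Abort if the number of subgraph instances exceeds this cap.
#' @return A `pep_fingerprint`.
#' @export
all_subgraph_fingerprint <- function(graph, max_bonds = 7L,
                                     variant = c("count", "binary"),
                                     cap = 1e7) {
  stopifnot(inherits(graph, "pep_graph"))
  variant <- match.arg(variant)
  if (max_bonds < 1 || max_bonds > 9)
    pep_abort("max_bonds must be in 1..9", "pep_config_error")
  df <- tryCatch(
    cpp_subgraph(graph_atom_matrix(graph), graph_bond_matrix(graph),
                 as.integer(max_bonds), cap),
    error = function(e) {
      if (grepl("cap", conditionMessage(e))) {
        pep_abort(conditionMessage(e), "pep_size_error", parent = e)
      }
      stop(e)
    })
  new_raw_fp(df, "all_subgraph", list(max_bonds = as.integer(max_bonds)),
             variant, nrow(graph$atoms))
}

#' Compute the fingerprint selected by a configuration
#'
#' @param graph A `pep_graph`.
#' @param config An [fp_config()].
#' @return A `pep_fingerprint`.
#' @export
fingerprint <- function(graph, config = fp_config()) {
  stopifnot(inherits(config, "fp_config"))
  switch(config$family,
    circular = circular_fingerprint(graph, config$radius, config$variant),
    torsion = torsion_fingerprint(graph, config$path_length, config$variant),
    all_subgraph = all_subgraph_fingerprint(graph, config$max_bonds,
                                            config$variant))
}

#' Fold a raw fingerprint to a fixed-length vector
#'
#' Maps each 64-bit key to `key mod n_bits`.  The count variant sums colliding
#' counts (so the folded vector always sums to the raw total count); the
#' binary variant sets an indicator.
#'
#' @param fp A `pep_fingerprint`.
#' @param n_bits Output length (default 2048).
#' @param variant `"count"` or `"binary"`; defaults to the variant recorded in
#'   `fp`.
#' @return Integer vector of length `n_bits` with attributes `family` and
#'   `variant`.
#' @export
fold_fingerprint <- function(fp, n_bits = 2048L, variant = NULL) {
  stopifnot(inherits(fp, "pep_fingerprint"))
  variant <- variant %||% fp$variant
  variant <- match.arg(variant, c("count", "binary"))
  n_bits <- as.integer(n_bits)
  if (is.na(n_bits) || n_bits < 1) {
    pep_abort("n_bits must be >= 1", "pep_config_error")
  }
  vec <- integer(n_bits)
  if (nrow(fp$counts) > 0) {
    idx <- hex_mod64(fp$counts$key, n_bits) + 1L
    agg <- rowsum(fp$counts$count, idx)
    vec[as.integer(rownames(agg))] <- as.integer(agg)
  }
  if (variant == "binary") vec <- as.integer(vec > 0)
  structure(vec, family = fp$family, variant = variant)
}

#' Featurize peptide sequences into a fingerprint matrix
#'
#' Builds the molecular graph of each sequence, computes the configured
#' fingerprint, and folds it into a row of a sparse matrix.  Row order follows
#' the input.
#'
#' @param data A data frame with a sequence column (and optionally an `id`
#'   column), or a character vector of sequences.
#' @param config An [fp_config()].
#' @param seq_col Sequence column name when `data` is a data frame.
#' @return A `pep_features` object: list with a sparse `matrix`
#'   (`Matrix::dgCMatrix`, rows = sequences, `n_bits` columns), `ids`, and the
#'   `config`.
#' @export
#' @examples
#' f <- featurize(c("G", "GG"), fp_config(n_bits = 64))
#' Matrix::rowSums(f$matrix)
featurize <- function(data, config = fp_config(), seq_col = "sequence") {
  stopifnot(inherits(config, "fp_config"))
  rs <- resolve_sequences(data, seq_col)
  seqs <- validate_sequences(rs$seqs)
  n <- length(seqs)
  if (n == 0) {
    return(new_pep_features(
      Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                           dims = c(0L, config$n_bits)),
      character(0), config))
  }
  # graphs (and hence folded rows) of identical sequences are identical
  uniq <- unique(seqs)
  rows <- vector("list", length(uniq))
  names(rows) <- uniq
  for (s in uniq) {
    fp <- tryCatch(
      fingerprint(build_peptide_graph(s), config),
      error = function(e) {
        id <- rs$ids[match(s, seqs)]
        pep_abort(sprintf("featurization failed for sequence id '%s': %s",
                          id, conditionMessage(e)),
                  class(e)[1], parent = e)
      })
    if (nrow(fp$counts) > 0) {
      idx <- hex_mod64(fp$counts$key, config$n_bits) + 1L
      agg <- rowsum(fp$counts$count, idx)
      rows[[s]] <- list(j = as.integer(rownames(agg)), x = as.numeric(agg))
    } else {
      rows[[s]] <- list(j = integer(0), x = numeric(0))
    }
  }
  per_seq <- rows[seqs]
  nnz <- vapply(per_seq, function(r) length(r$j), integer(1))
  mat <- Matrix::sparseMatrix(
    i = rep(seq_len(n), nnz),
    j = unlist(lapply(per_seq, `[[`, "j"), use.names = FALSE),
    x = unlist(lapply(per_seq, `[[`, "x"), use.names = FALSE),
    dims = c(n, config$n_bits))
  if (config$variant == "binary") {
    mat@x <- as.numeric(mat@x > 0)
  }
  new_pep_features(mat, rs$ids, config)
}

new_pep_features <- function(matrix, ids, config) {
  structure(list(matrix = matrix, ids = ids, config = config),
            class = "pep_features")
}

#' @export
print.pep_features <- function(x, ...) {
  cat(sprintf("<pep_features: %d x %d (%s, %s variant), %d nonzeros>\n",
              nrow(x$matrix), ncol(x$matrix), x$config$family,
              x$config$variant, length(x$matrix@x)))
  invisible(x)
}

#' @export
dim.pep_features <- function(x) dim(x$matrix)

#' @export
as.matrix.pep_features <- function(x, ...) as.matrix(x$matrix)

#' @export
as_tibble.pep_features <- function(x, ...) {
  out <- as_tibble(as.matrix(x$matrix), .name_repair = "minimal")
  names(out) <- paste0("bit", seq_len(ncol(x$matrix)) - 1L)
  dplyr::bind_cols(tibble(id = x$ids), out)
}
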