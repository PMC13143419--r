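#' Fingerprint configuration
#'
#' Bundles the family and hyperparameters of a hashed molecular fingerprint.
#' Defaults follow common practice for peptide property prediction: circular
#' radius 2 (diameter 4), torsion path length 4 atoms, all-subgraph limit 7
#' bonds, 2048 output bits, count variant.
#'
#' @param family `"circular"` (ECFP-style Morgan), `"torsion"` (topological
#'   torsion linear paths) or `"all_subgraph"` (all connected subgraphs up to
#'   a bond limit).
#' @param radius Circular fingerprint radius (non-negative integer).
#' @param path_length Torsion path length in atoms (>= 2).
#' @param max_bonds All-subgraph bond limit (1..9).
#' @param n_bits Folded vector length (positive integer).
#' @param variant `"count"` or `"binary"`.
#' @return An `fp_config` list.
#' @export
#' @examples
#' fp_config()                        # circular, radius 2, 2048 bits, count
#' fp_config("torsion", variant = "binary")
fp_config <- function(family = c("circular", "torsion", "all_subgraph"),
                      radius = 2L, path_length = 4L, max_bonds = 7L,
                      n_bits = 2048L, variant = c("count", "binary")) {
  family <- match.arg(family)
  variant <- match.arg(variant)
  radius <- as.integer(radius)
  path_length <- as.integer(path_length)
  max_bonds <- as.integer(max_bonds)
  n_bits <- as.integer(n_bits)
  if (is.na(radius) || radius < 0)
    pep_abort("radius must be >= 0", "pep_config_error")
  if (is.na(path_length) || path_length < 2)
    pep_abort("path_length must be >= 2", "pep_config_error")
  if (is.na(max_bonds) || max_bonds < 1 || max_bonds > 9)
    pep_abort("max_bonds must be in 1..9", "pep_config_error")
  if (is.na(n_bits) || n_bits < 1)
    pep_abort("n_bits must be >= 1", "pep_config_error")
  structure(list(family = family, radius = radius, path_length = path_length,
                 max_bonds = max_bonds, n_bits = n_bits, variant = variant),
            class = "fp_config")
}

#' @export
print.fp_config <- function(x, ...) {
  size <- switch(x$family,
    circular = sprintf("radius %d", x$radius),
    torsion = sprintf("path length %d", x$path_length),
    all_subgraph = sprintf("max %d bonds", x$max_bonds))
  cat(sprintf("<fp_config %s (%s), %d bits, %s variant>\n",
              x$family, size, x$n_bits, x$variant))
  invisible(x)
}

#' Hyperparameter tuning grids for each fingerprint family
#'
#' The subgraph-size ranges typically searched when tuning: circular radius
#' 2..4, torsion path length 4..6, all-subgraph bond limit 7..9.
#'
#' @param family Fingerprint family.
#' @return Integer vector of candidate sizes.
#' @export
fp_tuning_grid <- function(family = c("circular", "torsion", "all_subgraph")) {
  switch(match.arg(family),
         circular = 2:4, torsion = 4:6, all_subgraph = 7:9)
}
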