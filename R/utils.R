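# Classed conditions used across the package; the CLI maps each class to a
# distinct exit code.
pep_abort <- function(message, class, ...) {
  abort(message, class = c(class, "pep_error"), ...)
}

#' Derive a stream of independent seeds from a master seed
#'
#' Uses a splitmix64 counter stream so that experiment grid cells get
#' reproducible, mutually independent 31-bit seeds.
#'
#' @param master Master seed (single integerish value).
#' @param n Number of seeds to derive.
#' @return Integer vector of `n` seeds in `[0, 2^31)`.
#' @export
#' @examples
#' seed_stream(42, 3)
seed_stream <- function(master, n) {
  stopifnot(length(master) == 1, is.finite(master), n >= 0)
  as.integer(cpp_splitmix_seeds(as.numeric(master), as.integer(n)))
}

# bond order codes shared with the C++ core
bond_order_code <- function(order) {
  code <- c(single = 1L, double = 2L, aromatic = 4L)[order]
  if (anyNA(code)) {
    pep_abort(paste0("unknown bond order: ",
                     paste(unique(order[is.na(code)]), collapse = ", ")),
              "pep_chem_error")
  }
  unname(code)
}

element_z <- function(element) {
  z <- c(C = 6L, N = 7L, O = 8L, S = 16L)[element]
  if (anyNA(z)) {
    pep_abort(paste0("unsupported element: ",
                     paste(unique(element[is.na(z)]), collapse = ", ")),
              "pep_chem_error")
  }
  unname(z)
}

#' Canonical amino-acid alphabet
#'
#' The 20 canonical one-letter amino-acid codes, alphabetically ordered.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Monoisotopic residue masses
#'
#' Monoisotopic masses (Da) of amino-acid residues (i.e. the amino acid minus
#' water), used as the deterministic size proxy for synthetic regression
#' targets.
#' @export
RESIDUE_MASSES <- c(
  A = 71.03711, C = 103.00919, D = 115.02694, E = 129.04259, F = 147.06841,
  G = 57.02146, H = 137.05891, I = 113.08406, K = 128.09496, L = 113.08406,
  M = 131.04049, N = 114.04293, P = 97.05276, Q = 128.05858, R = 156.10111,
  S = 87.03203, T = 101.04768, V = 99.06841, W = 186.07931, Y = 163.06333
)

# Evaluate expr under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Validate a vector of peptide sequences; returns them uppercased.
validate_sequences <- function(seqs, what = "sequence") {
  if (length(seqs) == 0) return(character(0))
  if (!is.character(seqs)) {
    pep_abort(sprintf("%s must be a character vector", what), "pep_config_error")
  }
  seqs <- toupper(seqs)
  if (any(!nzchar(seqs) | is.na(seqs))) {
    bad <- which(!nzchar(seqs) | is.na(seqs))
    pep_abort(sprintf("empty %s at record %s", what,
                      paste(head(bad, 5), collapse = ", ")),
              "pep_input_error")
  }
  letters_used <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  unknown <- setdiff(letters_used, AA_ALPHABET)
  if (length(unknown) > 0) {
    first_bad <- which(vapply(seqs, function(s) {
      any(strsplit(s, "")[[1]] %in% unknown)
    }, logical(1)))[1]
    pep_abort(sprintf("unknown residue letter(s) %s (first in record %d)",
                      paste(sort(unknown), collapse = ", "), first_bad),
              "pep_chem_error")
  }
  seqs
}

# Resolve a sequence column from a data frame or accept a bare character
# vector; returns list(seqs, ids).
resolve_sequences <- function(data, seq_col = "sequence") {
  if (is.character(data)) {
    return(list(seqs = data, ids = names(data) %||% as.character(seq_along(data))))
  }
  if (is.data.frame(data)) {
    if (!seq_col %in% names(data)) {
      pep_abort(sprintf("no '%s' column in data", seq_col), "pep_config_error")
    }
    ids <- if ("id" %in% names(data)) as.character(data$id) else
      as.character(seq_len(nrow(data)))
    return(list(seqs = as.character(data[[seq_col]]), ids = ids))
  }
  pep_abort("data must be a data frame or character vector", "pep_config_error")
}
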