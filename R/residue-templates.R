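# Embedded per-residue chemistry tables (hydrogen-suppressed, neutral forms).
#
# Each template describes the internal-residue form: backbone N, CA, C and
# carbonyl O plus the side chain.  Implicit hydrogen counts are stored for the
# mid-chain context (amide N carries one H, none for proline); the graph
# builder adds one H at the N-terminus and a hydroxyl oxygen at the
# C-terminus.  Aromatic systems (Phe, Tyr, Trp, His) are precomputed; His uses
# the N-delta-H tautomer.  All atoms are neutral: free amine, carboxylic acid,
# and neutral Lys/Arg/Asp/Glu side chains.

# atoms: "name element nH aromatic_flag", bonds: "a b order" with order
# s(ingle), d(ouble), a(romatic).
.tpl_def <- list(
  G = list(atoms = "
    N  N 1 -
    CA C 2 -
    C  C 0 -
    O  O 0 -",
    bonds = "N CA s; CA C s; C O d"),
  A = list(atoms = "
    N  N 1 -
    CA C 1 -
    C  C 0 -
    O  O 0 -
    CB C 3 -",
    bonds = "N CA s; CA C s; C O d; CA CB s"),
  V = list(atoms = "
    N   N 1 -
    CA  C 1 -
    C   C 0 -
    O   O 0 -
    CB  C 1 -
    CG1 C 3 -
    CG2 C 3 -",
    bonds = "N CA s; CA C s; C O d; CA CB s; CB CG1 s; CB CG2 s"),
  L = list(atoms = "
    N   N 1 -
    CA  C 1 -
    C   C 0 -
    O   O 0 -
    CB  C 2 -
    CG  C 1 -
    CD1 C 3 -
    CD2 C 3 -",
    bonds = "N CA s; CA C s; C O d; CA CB s; CB CG s; CG CD1 s; CG CD2 s"),
  I = list(atoms = "
    N   N 1 -
    CA  C 1 -
    C   C 0 -
    O   O 0 -
    CB  C 1 -
    CG1 C 2 -
    CG2 C 3 -
    CD1 C 3 -",
    bonds = "N CA s; CA C s; C O d; CA CB s; CB CG1 s; CB CG2 s; CG1 CD1 s"),
  P = list(atoms = "
    N  N 0 -
    CA C 1 -
    C  C 0 -
    O  O 0 -
    CB C 2 -
    CG C 2 -
    CD C 2 -",
    bonds = "N CA s; CA C s; C O d; CA CB s; CB CG s; CG CD s; CD N s"),
  F = list(atoms = "
    N   N 1 -
    CA  C 1 -
    C   C 0 -
    O   O 0 -
    CB  C 2 -
    CG  C 0 a
    CD1 C 1 a
    CD2 C 1 a
    CE1 C 1 a
    CE2 C 1 a
    CZ  C 1 a",
    bonds = "N CA s; CA C s; C O d; CA CB s; CB CG s; CG CD1 a; CD1 CE1 a; CE1 CZ a; CZ CE2 a; CE2 CD2 a; CD2 CG a"),
  Y = list(atoms = "
    N   N 1 -
    CA  C 1 -
    C   C 0 -
    O   O 0 -
    CB  C 2 -
    CG  C 0 a
    CD1 C 1 a
    CD2 C 1 a
    CE1 C 1 a
    CE2 C 1 a
    CZ  C 0 a
    OH  O 1 -",
    bonds = "N CA s; CA C s; C O d; CA CB s; CB CG s; CG CD1 a; CD1 CE1 a; CE1 CZ a; CZ CE2 a; CE2 CD2 a; CD2 CG a; CZ OH s"),
  W = list(atoms = "
    N   N 1 -
    CA  C 1 -
    C   C 0 -
    O   O 0 -
    CB  C 2 -
    CG  C 0 a
    CD1 C 1 a
    NE1 N 1 a
    CE2 C 0 a
    CD2 C 0 a
    CE3 C 1 a
    CZ3 C 1 a
    CH2 C 1 a
    CZ2 C 1 a",
    bonds = "N CA s; CA C s; C O d; CA CB s; CB CG s; CG CD1 a; CD1 NE1 a; NE1 CE2 a; CE2 CD2 a; CD2 CG a; CD2 CE3 a; CE3 CZ3 a; CZ3 CH2 a; CH2 CZ2 a; CZ2 CE2 a"),
  H = list(atoms = "
    N   N 1 -
    CA  C 1 -
    C   C 0 -
    O   O 0 -
    CB  C 2 -
    CG  C 0 a
    ND1 N 1 a
    CE1 C 1 a
    NE2 N 0 a
    CD2 C 1 a",
    bonds = "N CA s; CA C s; C O d; CA CB s; CB CG s; CG ND1 a; ND1 CE1 a; CE1 NE2 a; NE2 CD2 a; CD2 CG a"),
  S = list(atoms = "
    N  N 1 -
    CA C 1 -
    C  C 0 -
    O  O 0 -
    CB C 2 -
    OG O 1 -",
    bonds = "N CA s; CA C s; C O d; CA CB s; CB OG s"),
  T = list(atoms = "
    N   N 1 -
    CA  C 1 -
    C   C 0 -
    O   O 0 -
    CB  C 1 -
    OG1 O 1 -
    CG2 C 3 -",
    bonds = "N CA s; CA C s; C O d; CA CB s; CB OG1 s; CB CG2 s"),
  C = list(atoms = "
    N  N 1 -
    CA C 1 -
    C  C 0 -
    O  O 0 -
    CB C 2 -
    SG S 1 -",
    bonds = "N CA s; CA C s; C O d; CA CB s; CB SG s"),
  M = list(atoms = "
    N  N 1 -
    CA C 1 -
    C  C 0 -
    O  O 0 -
    CB C 2 -
    CG C 2 -
    SD S 0 -
    CE C 3 -",
    bonds = "N CA s; CA C s; C O d; CA CB s; CB CG s; CG SD s; SD CE s"),
  N = list(atoms = "
    N   N 1 -
    CA  C 1 -
    C   C 0 -
    O   O 0 -
    CB  C 2 -
    CG  C 0 -
    OD1 O 0 -
    ND2 N 2 -",
    bonds = "N CA s; CA C s; C O d; CA CB s; CB CG s; CG OD1 d; CG ND2 s"),
  Q = list(atoms = "
    N   N 1 -
    CA  C 1 -
    C   C 0 -
    O   O 0 -
    CB  C 2 -
    CG  C 2 -
    CD  C 0 -
    OE1 O 0 -
    NE2 N 2 -",
    bonds = "N CA s; CA C s; C O d; CA CB s; CB CG s; CG CD s; CD OE1 d; CD NE2 s"),
  D = list(atoms = "
    N   N 1 -
    CA  C 1 -
    C   C 0 -
    O   O 0 -
    CB  C 2 -
    CG  C 0 -
    OD1 O 0 -
    OD2 O 1 -",
    bonds = "N CA s; CA C s; C O d; CA CB s; CB CG s; CG OD1 d; CG OD2 s"),
  E = list(atoms = "
    N   N 1 -
    CA  C 1 -
    C   C 0 -
    O   O 0 -
    CB  C 2 -
    CG  C 2 -
    CD  C 0 -
    OE1 O 0 -
    OE2 O 1 -",
    bonds = "N CA s; CA C s; C O d; CA CB s; CB CG s; CG CD s; CD OE1 d; CD OE2 s"),
  K = list(atoms = "
    N  N 1 -
    CA C 1 -
    C  C 0 -
    O  O 0 -
    CB C 2 -
    CG C 2 -
    CD C 2 -
    CE C 2 -
    NZ N 2 -",
    bonds = "N CA s; CA C s; C O d; CA CB s; CB CG s; CG CD s; CD CE s; CE NZ s"),
  R = list(atoms = "
    N   N 1 -
    CA  C 1 -
    C   C 0 -
    O   O 0 -
    CB  C 2 -
    CG  C 2 -
    CD  C 2 -
    NE  N 1 -
    CZ  C 0 -
    NH1 N 1 -
    NH2 N 2 -",
    bonds = "N CA s; CA C s; C O d; CA CB s; CB CG s; CG CD s; CD NE s; NE CZ s; CZ NH1 d; CZ NH2 s")
)

.parse_tpl <- function(letter, def) {
  lines <- strsplit(trimws(def$atoms), "\n")[[1]]
  fields <- lapply(trimws(lines), function(l) strsplit(l, "\\s+")[[1]])
  atoms <- tibble(
    name = vapply(fields, `[[`, character(1), 1),
    element = vapply(fields, `[[`, character(1), 2),
    formal_charge = 0L,
    n_implicit_H = as.integer(vapply(fields, `[[`, character(1), 3)),
    aromatic = vapply(fields, `[[`, character(1), 4) == "a"
  )
  bond_specs <- strsplit(trimws(strsplit(def$bonds, ";")[[1]]), "\\s+")
  order_map <- c(s = "single", d = "double", a = "aromatic")
  bonds <- tibble(
    from = match(vapply(bond_specs, `[[`, character(1), 1), atoms$name),
    to = match(vapply(bond_specs, `[[`, character(1), 2), atoms$name),
    order = unname(order_map[vapply(bond_specs, `[[`, character(1), 3)])
  )
  if (anyNA(bonds$from) || anyNA(bonds$to) || anyNA(bonds$order)) {
    stop("malformed template for ", letter)
  }
  # ring membership of template atoms (edges not bridges)
  g <- igraph::graph_from_edgelist(cbind(bonds$from, bonds$to), directed = FALSE)
  bridges <- igraph::bridges(g)
  in_ring <- rep(FALSE, nrow(atoms))
  if (nrow(bonds) > 0) {
    ring_edges <- setdiff(seq_len(nrow(bonds)), as.integer(bridges))
    in_ring[unique(c(bonds$from[ring_edges], bonds$to[ring_edges]))] <- TRUE
  }
  atoms$in_ring <- in_ring
  structure(
    list(letter = letter,
         atoms = atoms,
         bonds = bonds,
         n_attach = match("N", atoms$name),
         c_attach = match("C", atoms$name)),
    class = "residue_template"
  )
}

.tpl_cache <- new.env(parent = emptyenv())

#' Look up the embedded template for a canonical amino acid
#'
#' Templates describe the internal-residue form of each amino acid as a
#' hydrogen-suppressed heavy-atom graph: backbone N, CA, C and carbonyl O plus
#' the side chain, with implicit-hydrogen counts, precomputed aromatic flags,
#' and the backbone attachment points used to chain residues into a peptide.
#'
#' @param letter One-letter amino-acid code (one of the 20 canonical letters).
#' @return A `residue_template`: list with `letter`, `atoms` (tibble with
#'   columns `name`, `element`, `formal_charge`, `n_implicit_H`, `aromatic`,
#'   `in_ring`), `bonds` (tibble `from`, `to`, `order`), and backbone
#'   attachment indices `n_attach`, `c_attach`.
#' @export
#' @examples
#' residue_template("G")$atoms
residue_template <- function(letter) {
  if (!is.character(letter) || length(letter) != 1 || is.na(letter)) {
    pep_abort("letter must be a single character", "pep_config_error")
  }
  letter <- toupper(letter)
  if (!letter %in% AA_ALPHABET) {
    pep_abort(sprintf("unknown residue letter '%s'", letter), "pep_chem_error")
  }
  if (is.null(.tpl_cache[[letter]])) {
    .tpl_cache[[letter]] <- .parse_tpl(letter, .tpl_def[[letter]])
  }
  .tpl_cache[[letter]]
}

#' @export
print.residue_template <- function(x, ...) {
  cat(sprintf("<residue_template %s: %d heavy atoms, %d bonds>\n",
              x$letter, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}
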