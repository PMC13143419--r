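test_that("micro peptides have the hand-counted atom and bond totals", {
  g1 <- build_peptide_graph("G")
  expect_identical(nrow(g1$atoms), 5L) # free glycine NCC(=O)O
  expect_identical(nrow(g1$bonds), 4L)
  g2 <- build_peptide_graph("GG")
  expect_identical(nrow(g2$atoms), 9L)
  expect_identical(nrow(g2$bonds), 8L)
  g3 <- build_peptide_graph("GGG")
  expect_identical(nrow(g3$atoms), 13L)
  expect_identical(nrow(g3$bonds), 12L)
})

test_that("degenerate inputs raise classed errors", {
  expect_error(build_peptide_graph(""), class = "pep_input_error")
  expect_error(build_peptide_graph("GXG"), "X", class = "pep_chem_error")
  expect_error(build_peptide_graph(c("GG", "AA")), class = "pep_config_error")
})

test_that("graph construction is deterministic to the byte", {
  g1 <- build_peptide_graph("WHPKACDE")
  g2 <- build_peptide_graph("WHPKACDE")
  expect_identical(g1, g2)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_graphs_jsonl(g1, f1)
  write_graphs_jsonl(g2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("heavy-atom counts are additive over residues plus the terminal oxygen", {
  tpl_sizes <- vapply(AA_ALPHABET,
                      function(a) nrow(residue_template(a)$atoms), integer(1))
  tpl_rings <- vapply(AA_ALPHABET, function(a) {
    tpl <- residue_template(a)
    nrow(tpl$bonds) - (nrow(tpl$atoms) - 1L) # ring bonds = extra bonds
  }, integer(1))
  for (s in random_peptides(25, max_len = 10, seed = 101)) {
    g <- build_peptide_graph(s)
    letters <- strsplit(s, "")[[1]]
    expect_identical(nrow(g$atoms), sum(tpl_sizes[letters]) + 1L)
    expect_identical(nrow(g$bonds),
                     nrow(g$atoms) - 1L + sum(tpl_rings[letters]))
  }
})

test_that("atom ordering is residue-major with the terminal oxygen last", {
  g <- build_peptide_graph("AG")
  expect_true(all(diff(g$atoms$residue) >= 0))
  expect_identical(g$atoms$name[nrow(g$atoms)], "OXT")
  expect_identical(g$atoms$element[nrow(g$atoms)], "O")
  # N-terminal amine has one more H than the interior amide nitrogen
  n_rows <- which(g$atoms$name == "N")
  expect_identical(g$atoms$n_implicit_H[n_rows], c(2L, 1L))
})

test_that("ring membership is recomputed and marks exactly the ring systems", {
  g <- build_peptide_graph("AFA")
  phe_ring <- g$atoms$name %in% c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  expect_identical(g$atoms$in_ring, phe_ring)
  g_pro <- build_peptide_graph("GPG")
  pro <- g_pro$atoms$residue == 2L & g_pro$atoms$name %in%
    c("N", "CA", "CB", "CG", "CD")
  expect_identical(g_pro$atoms$in_ring, pro)
})

test_that("JSON-lines serialization round-trips", {
  graphs <- lapply(c("GG", "WH"), build_peptide_graph)
  path <- withr::local_tempfile()
  write_graphs_jsonl(graphs, path)
  back <- read_graphs_jsonl(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$atoms, graphs[[1]]$atoms)
  expect_equal(back[[2]]$bonds, graphs[[2]]$bonds)
  expect_identical(back[[2]]$sequence, "WH")
  expect_error(read_graphs_jsonl(file.path(tempdir(), "nope.jsonl")),
               class = "pep_io_error")
})

test_that("graphs agree with an independent chemistry toolkit", {
  # cross-oracle: all 20 single residues plus 50 random peptides must be
  # isomorphic (element, bond order, aromaticity) to molecules built by
  # RDKit's sequence reader, checked via networkx
  python <- Sys.which("python")
  expect_true(nzchar(python), label = "python interpreter available")
  seqs <- c(AA_ALPHABET, random_peptides(50, max_len = 6, seed = 2024))
  jsonl <- withr::local_tempfile(fileext = ".jsonl")
  write_graphs_jsonl(lapply(seqs, build_peptide_graph), jsonl)
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import json, sys",
    "import networkx as nx",
    "from rdkit import Chem",
    "from networkx.algorithms import isomorphism",
    "bt = {Chem.BondType.SINGLE: 'single', Chem.BondType.DOUBLE: 'double',",
    "      Chem.BondType.AROMATIC: 'aromatic'}",
    "bad = []",
    "for line in open(sys.argv[1]):",
    "    o = json.loads(line)",
    "    G = nx.Graph()",
    "    for i, a in enumerate(o['atoms']):",
    "        G.add_node(i, element=a['element'], aromatic=a['aromatic'])",
    "    for b in o['bonds']:",
    "        G.add_edge(b['from'] - 1, b['to'] - 1, order=b['order'])",
    "    mol = Chem.MolFromSequence(o['sequence'])",
    "    H = nx.Graph()",
    "    for a in mol.GetAtoms():",
    "        H.add_node(a.GetIdx(), element=a.GetSymbol(),",
    "                   aromatic=a.GetIsAromatic())",
    "    for b in mol.GetBonds():",
    "        H.add_edge(b.GetBeginAtomIdx(), b.GetEndAtomIdx(),",
    "                   order=bt[b.GetBondType()])",
    "    nH_mine = sum(a['n_implicit_H'] for a in o['atoms'])",
    "    nH_ref = sum(a.GetTotalNumHs() for a in mol.GetAtoms())",
    "    gm = isomorphism.GraphMatcher(",
    "        G, H,",
    "        node_match=lambda x, y: x['element'] == y['element']",
    "        and x['aromatic'] == y['aromatic'],",
    "        edge_match=lambda x, y: x['order'] == y['order'])",
    "    if not (G.number_of_nodes() == H.number_of_nodes()",
    "            and G.number_of_edges() == H.number_of_edges()",
    "            and nH_mine == nH_ref and gm.is_isomorphic()):",
    "        bad.append(o['sequence'])",
    "print(json.dumps(bad))"), script)
  out <- system2(python, c(script, jsonl), stdout = TRUE)
  expect_identical(jsonlite::fromJSON(out[length(out)]), list())
})
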