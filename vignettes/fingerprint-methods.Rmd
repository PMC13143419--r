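---
title: "Molecular fingerprints for peptide function prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular fingerprints for peptide function prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepfp)
```

## The model

`pepfp` predicts peptide properties from the *topological molecular graph* of
the peptide rather than from its sequence or its folded structure.  The
pipeline has three deterministic stages:

1. **Graph construction.** The amino-acid sequence is expanded into a
   hydrogen-suppressed heavy-atom graph using embedded residue templates
   chained N-to-C by single peptide bonds.
2. **Fingerprinting.** Small subgraphs are exhaustively extracted and hashed
   into 64-bit identifiers; occurrence counts are folded into a fixed-length
   vector by modulo indexing.
3. **Boosted trees.** One gradient-boosted-tree model per task is trained on
   the folded count vectors, with class weights inversely proportional to the
   positive-class frequency on imbalanced binary tasks.

All three fingerprint families are strictly *short-range* descriptors: a
circular environment of radius 2 spans a 4-bond diameter, a torsion path
covers 4 consecutive atoms, and the all-subgraph family is capped at 7 bonds.
The scientific point of the package is that such local subgraph statistics,
in their **count** (not binary) variant, are strong peptide-function
predictors, and the included control experiments probe exactly where that
representation succeeds (composition- and size-driven properties) and where
it fails (order-dependent sequence motifs).

## Graph construction conventions

The residue templates record, per heavy atom: element (C/N/O/S for the
canonical 20), implicit hydrogen count, formal charge, aromaticity flag, and
ring membership.  Several conventions are deliberate and documented because
sequence input underdetermines the chemistry:

* **Hydrogens** are implicit (stored as per-atom counts), the standard
  fingerprint convention.
* **Protonation**: all atoms are neutral — free amine N-terminus, carboxylic
  acid C-terminus, neutral Lys/Arg/His/Asp/Glu side chains.  Sequence input
  carries no pH information, and fingerprints on neutral forms are the common
  default.
* **Aromaticity** is precomputed in the templates (benzene ring of Phe/Tyr,
  indole of Trp, imidazole of His) rather than perceived at run time, which
  keeps construction deterministic.  Histidine uses the Nδ-H tautomer; the
  choice is fixed and only affects implicit-hydrogen placement, not the heavy
  topology.
* **Termini**: the N-terminal nitrogen gains one implicit hydrogen; the
  C-terminus gains one hydroxyl oxygen appended as the last atom.  Heavy-atom
  count is therefore always the sum of template sizes plus one.
* **Cross-links**: disulfide bridges are never formed (sequence input has no
  pairing information); cysteines stay reduced.  Stereochemistry is ignored —
  the graphs are purely topological.
* **Ring flags** are recomputed from the assembled graph by bridge detection
  rather than trusted from the templates.

The unit tests validate every template and 70 assembled graphs against an
independent chemistry toolkit by graph isomorphism (element, bond order,
aromaticity) and by total hydrogen count.

## Hashing and the fingerprint dialect

Substructure identifiers must be stable across runs and platforms, so all
hashing uses a seedless 64-bit FNV-1a over canonical ASCII encodings (the
exact layouts are documented at the top of `R/fingerprints.R`).  Collisions
below $2^{64}$ are accepted; the folded vector additionally collides keys by
`key mod n_bits`, which is the standard folding scheme.

Specific choices where published descriptions leave latitude:

* **Initial atom invariant**: (atomic number, heavy degree, total H count,
  formal charge, ring flag, total bond-order valence).  Published invariant
  lists mention "a few other simple features"; this tuple is our fixed
  dialect.
* **Circular deduplication**: among environments covering identical bond
  sets, the smallest radius survives, ties broken by smaller identifier.
  Radius-0 instances are always kept (one per atom).  The surviving instance
  totals at radius 2 agree exactly with a reference implementation's Morgan
  count fingerprints on test peptides, which is checked in the suite.
* **Torsion atom types**: (atomic number, π-electron count, heavy degree),
  terminal degrees decremented by one; π electrons are derived from bond
  orders (order sum minus degree) rather than perceived electronically.
  Ring membership is *not* part of the torsion type — a flagged sensitivity
  choice, since published descriptions are silent on it.
* **Aromatic bonds** hash as their own bond-order code; no Kekulé assignment
  is ever made, again for determinism.
* **Counting semantics**: one count per surviving instance (environment,
  path, or edge-subset occurrence), never per unique key.  This is what makes
  count fingerprints size-aware.

The all-subgraph family enumerates every connected edge-induced subgraph up
to the bond cap exactly once and canonicalizes each by branch-and-prune
minimization over vertex orderings — feasible because subgraphs have at most
`max_bonds + 1` vertices.  A configurable instance cap (default $10^7$)
guards against combinatorial blow-up on pathological inputs.

## Testing strategy: oracles

Every fingerprint family is checked against an independent brute-force
enumeration (`enumerate_substructures()`): circular environments by BFS ball
bond sets with identifiers recomputed by a memoized top-down recursion,
torsion paths by igraph's simple-path enumeration, and subgraphs by a
breadth-first closure over edge subsets with an explicit visited set.  The
acceptance suite requires *exact* agreement of per-key multiplicities on 50
seeded random peptides.  Metric implementations (AUROC, average precision)
are likewise compared against brute-force pairwise concordance and a direct
tie-grouped precision-recall computation.

## The modeling layer

The boosted-tree backend is xgboost with histogram trees, single-threaded for
reproducibility; only the tree count (default 500) is pinned, all other
hyperparameters stay at the backend defaults.  Binary tasks use the log-loss
objective with optional class weights $w_\mathrm{pos} = n_\mathrm{neg} /
n_\mathrm{pos}$, $w_\mathrm{neg} = 1$; regression tasks optimize mean
absolute error.  Multi-output datasets train one model per target column; a
degenerate column (single class) is recorded as a per-task error without
aborting the remaining tasks.

Evaluation reports average precision (non-interpolated, ties grouped by
equal scores — with constant scores it degrades to the prevalence), AUROC by
the Mann–Whitney rank formula with mid-rank tie correction, MCC and F1 at a
fixed 0.5 threshold (published comparisons are silent on thresholds, so we
match default classifier behavior), and MAE for regression.  Metrics that
are undefined on a single-class test column are excluded from task averages
with a warning, never silently zeroed.

## The synthetic generator and what it emulates

Because the public peptide benchmarks require large downloads and external
homology-clustering tools, the package ships a generator
(`generate_peptides()`) whose planted labels make the control experiments
reproducible at desk scale:

* **Composition rule** — positive iff the fraction of designated letters
  (default K/R, cutoff 0.15) exceeds a threshold.  Emulates properties driven
  by residue composition (e.g. cationic antimicrobial peptides); labels are
  order-invariant by construction.
* **Motif rule** — positive iff a contiguous motif (default "KKK"/"RRR")
  occurs.  Emulates order-dependent, long-range recognition; trivially
  learnable from n-grams, hard for short-range atom-level features.
* **Size regression** — target is the summed monoisotopic residue mass, the
  simplest deterministic size functional; emulates regression targets that
  correlate strongly with peptide size.

Defaults are 20-letter uniform composition, lengths uniform on 10–50
residues (the typical peptide range), zero label noise, and natural class
rates; the motif task uses rejection sampling to a 0.3 positive fraction so
both classes are well represented.  Sequences are i.i.d.; the generator does
**not** emulate homology structure, residue autocorrelation, or
length-matched negative sampling of real benchmarks, so passing control
experiments demonstrate the *qualitative* mechanisms (count-vs-binary,
shuffling robustness, motif blindness), not benchmark-level accuracy.

## The control experiments

All three experiments run at n = 2000 training / 500 test sequences over 5
derived seeds (a size that keeps the full suite within a few minutes on one
core while leaving the qualitative effects far from their decision
boundaries):

1. **Count vs. binary** (`count_vs_binary_ablation()`): on size regression,
   count features encode molecule size while binary features saturate, so
   count MAE is far lower; appending an explicit sequence-length column
   recovers part, but only part, of the gap.
2. **Sequence shuffling** (`run_shuffle_experiment()`): a fraction of
   residue positions in each training sequence is permuted (the selected
   multiset is permuted in place, fixed points allowed — the simplest null
   that exactly preserves composition; test sequences stay untouched, with a
   flag for the test-side variant).  On a composition task even full
   shuffling moves test AUROC by well under 0.05, because the labels and the
   dominant fingerprint features are both order-insensitive.  Monotone
   degradation is *not* asserted — small non-monotone wiggles are expected.
3. **Motif stress test** (`motif_stress_test()`): an n-gram baseline with
   trigram counts sees the "KKK" feature directly and reaches AUROC ≥ 0.99,
   while the fingerprint model, which can only see charged side chains
   without their sequence adjacency, trails it in every paired replicate.
   This delineates the representation's failure mode.

Per-cell seeds are derived from a master seed with a splitmix64 counter
stream (`seed_stream()`), so grid cells are independent and each cell's seed
is recorded in the output.

## Numerical and degenerate-input choices

* Identifiers are compared as fixed-width lowercase hex strings, whose
  lexicographic order equals the unsigned 64-bit numeric order.
* Folding uses true unsigned 64-bit modulo (computed in C++), not floating
  point.
* Empty sequence sets featurize to a 0-row matrix; single-atom graphs are
  legal fingerprint inputs (all higher-radius environments deduplicate onto
  radius 0).
* `class_weights()` refuses single-class labels with a distinct error class,
  which the CLI maps to its own exit code.
* The torsion canonical orientation compares numeric type tuples, so
  palindromic paths hash identically from both ends.

## Known limitations

* Only the 20 canonical residues are supported; chemically modified, cyclic,
  and disulfide-bridged peptides are out of scope (the graphs would need
  cross-link records that plain sequences do not carry).
* Fingerprint keys are a documented dialect: stable within the package, not
  bit-compatible with other toolkits (totals and instance semantics are
  compatible, which is what the cross-implementation test checks).
* The boosted-tree layer exposes only the tree count; full hyperparameter
  search is deliberately out of scope.
* Synthetic data is i.i.d. over residues; conclusions about homology-split
  generalization on real benchmarks cannot be drawn from it.

## Reproducing the numbers

The package's own headline quantities are recomputed from scratch by
`scripts/acceptance.R` (see the README), which runs the worked
micro-examples, the 50-peptide oracle-equivalence sweep, and the full
control suite at the sizes above, and writes one JSON object with every
measured value.
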