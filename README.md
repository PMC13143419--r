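# pepfp — count-based molecular fingerprints for peptide function prediction

`pepfp` predicts peptide properties (antimicrobial activity, toxicity,
physicochemical targets, …) from the peptide's **atom-level topological
graph** instead of its raw sequence or folded structure.  It is aimed at
bioinformaticians who want a strong, fast, deterministic baseline for peptide
classification and regression, and at researchers studying whether such tasks
actually require long-range interaction modeling.

## The method

1. **Sequence → molecular graph.** Each amino-acid sequence is expanded into
   a hydrogen-suppressed heavy-atom graph from embedded residue templates,
   chained N→C by peptide bonds (free amine N-terminus, carboxylic acid
   C-terminus, all atoms neutral).
2. **Graph → hashed fingerprint.** Three families of small subgraphs are
   enumerated and hashed into 64-bit identifiers:
   * *circular* — Morgan/ECFP-style atom environments of radius $r \le 2$
     (diameter 4), with Rogers–Hahn bond-set deduplication;
   * *torsion* — typed linear paths of 4 atoms;
   * *all-subgraph* — every connected edge-induced subgraph with ≤ 7 bonds,
     keyed by canonical labeled form.

   Occurrence **counts** $c_k$ of each substructure key $k$ are folded into a
   fixed-length vector by modulo indexing, $x_{k \bmod B} \mathrel{+}= c_k$
   with $B = 2048$ bits; the binary variant stores only indicators.
3. **Fingerprint → prediction.** One gradient-boosted-tree model (500 trees)
   per task, with class weights $w_{\text{pos}} = n_{\text{neg}} /
   n_{\text{pos}}$, $w_{\text{neg}} = 1$ on imbalanced binary tasks and an
   MAE objective for regression.  Metrics: AUPRC (average precision), AUROC,
   MCC, F1, MAE.

The package also implements the control experiments that probe this
representation — sequence shuffling, count-vs-binary ablation, and a charged
sequence-motif ("KKK"/"RRR") stress test — together with a synthetic peptide
generator with planted composition, motif, and size-regression labels, and
exact brute-force enumeration oracles for every fingerprint family.

## Worked example

```r
library(pepfp)

g <- build_peptide_graph("GWKK")
g
#> <pep_graph "GWKK": 37 heavy atoms, 38 bonds>

fp <- circular_fingerprint(g, radius = 2)
fp
#> <pep_fingerprint circular: 53 keys, 103 instances (count variant)>
```

37 heavy atoms: Gly (4) + Trp (14) + 2×Lys (9) + the terminal hydroxyl
oxygen.  103 instances are the surviving (atom, radius) environments after
deduplication — 37 at radius 0 plus the distinct radius-1/2 neighborhoods —
distributed over 53 distinct substructure keys.

```r
spec <- synthetic_spec(n = 600, label_rule = "motif",
                       motifs = c("KKK", "RRR"), imbalance = 0.3, seed = 42)
data <- generate_peptides(spec)          # tibble: id, sequence, label
train <- data[1:450, ]; test <- data[451:600, ]

features <- featurize(train, fp_config())
features
#> <pep_features: 450 x 2048 (circular, count variant), 60949 nonzeros>

fit <- fit_peptide_model(features, train[, "label"])
scores <- predict(fit, featurize(test, fp_config()))
glance(evaluate_predictions(scores, test[, "label"]))
#> # A tibble: 1 × 5
#>   auprc auroc    f1   mcc n_tasks
#>   <dbl> <dbl> <dbl> <dbl>   <int>
#> 1 0.616 0.853 0.667 0.510       1
```

An AUROC of ~0.85 on a motif task is exactly the expected *partial* success:
the fingerprint sees the lysine-rich composition that correlates with "KKK"
but not the motif's adjacency itself.  The same pipeline on a
composition-threshold task scores ~0.99, and `motif_stress_test()` shows a
trigram baseline reaching ≥ 0.99 here — that contrast is the package's
central control experiment.

Experiment helpers return tidy tibbles with `autoplot()` methods:

```r
res <- run_shuffle_experiment(train, test, ratios = c(0, 0.5, 1))
autoplot(res)
abl <- count_vs_binary_ablation(train, test)
attr(abl, "delta")      # count-minus-binary metric deltas
```

A thin command-line interface wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/pepfp.R", package="pepfp"))') \
    featurize --input peptides.fasta --output feats --n-bits 2048
```

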