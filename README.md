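# cmorph — hard-to-synthesize structures by complexity-bounded molecular morphing

Machine-learning models of synthetic accessibility need hard-to-synthesize
training molecules, and no database of those exists. `cmorph` generates
them: a starting structure from a library of accessible compounds
undergoes a stochastic walk of elementary graph edits — add / remove /
mutate an atom or a bond — and the walk is stopped at the **first** step
whose structural complexity exceeds what is normal for accessible
molecules of that size. The products are implausible to make, but not
absurdly so, which is exactly what a binary easy/hard classifier needs as
its negative class.

The stop signal combines four complexity indices — Bertz (graph
information content), Whitlock (`4·rings + 2·unsaturations +
1·heteroatoms + 2·stereocenters`), an additive Barone–Chanon index and an
SMCM-style atom/bond/ring/chirality sum — with thresholds calibrated from
a reference library per 50-Da molecular-weight bin (eleven bins, values
clamped above 550 Da) at three levels: the observed maximum, the 999th
permille and the 99th percentile (nearest rank). A morph is *hard* when
at least *k* of the four indices strictly exceed their bin threshold; the
default stop condition is `p999, k = 1`. Paths are capped at 30 steps.

For benchmarking, the package also builds easy/hard sets by two competing
strategies — SAscore thresholds (hard > 6, easy < 4, scores consumed as an
input column) and dense-region density labels (easy ≥ 20 neighbors at
Tanimoto ≥ 0.6 on 512-bit radius-2 circular fingerprints, hard ≤ 1) — and
evaluates all of them with a 100-tree random-forest classifier (accuracy,
sensitivity, specificity, ROC/AUC, five-sample averaging).

## Worked example

```r
library(cmorph)

# a deterministic synthetic library spanning all eleven MW bins
lib <- fixture_library(1100, seed = 101)
tab <- calibrate_thresholds(lib, id = "fixture")
tab
#> <threshold_table: 11 bins x 50 Da, library 'fixture' (n=1100), 0 empty bin(s)>

# morph one structure until it crosses the thresholds
path <- morph_until_complex(lib[[42]], tab, stop_condition("p999", 1),
                            seed = 1)
path
#> <morph_path: 23 step(s), status HIT>

# a whole library of hard structures, deduplicated by canonical SMILES
gl <- generate_library(lib[1:100], tab, seed = 5)
gl
#> <morph_library: 46 hard structures from 100 paths (46 HIT / 54 EXHAUSTED / 0 DEAD_END)>

# pair the hard morphs with their starting structures and benchmark
built <- build_nonpher_sets(lib[1:100], tab, easy_from = "starts", seed = 5)
clf <- train_classifier(built$set, n_trees = 100, seed = 1)
evaluate_classifier(clf, built$set)
#> <eval_report: Acc 100.0% | SN 100.0% | SP 100.0% | AUC 1.000>
```

(The last line evaluates on the training set itself and is only a
plumbing check; held-out evaluation numbers come from `repeat_eval()` and
the acceptance script below.)

The confusion-matrix arithmetic on the canonical 120-easy / 40-hard test
composition, with 9 false negatives and 8 false positives:

```r
metrics(c(TP = 111, TN = 32, FP = 8, FN = 9))
#>     acc      sn      sp
#> 0.89375 0.92500 0.80000
```

i.e. 89.4% accuracy, 92.5% sensitivity, 80% specificity.

A command-line front end with `calibrate`, `morph`, `build-sets`,
`evaluate`, `grid`, `fixtures` and `pipeline` subcommands lives at
`inst/cli/cmorph.R`.

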