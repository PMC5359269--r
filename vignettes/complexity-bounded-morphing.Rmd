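---
title: "Complexity-bounded molecular morphing: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complexity-bounded molecular morphing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Supervised models of synthetic accessibility need both easy- and
hard-to-synthesize training molecules. Catalogs of purchasable compounds
supply the easy class in abundance; no database of hard-to-synthesize
structures exists, because nobody stocks molecules that cannot be made.
`cmorph` manufactures that missing negative class. A starting structure
drawn from an accessible library undergoes a random walk of elementary
graph edits — add, remove or mutate an atom or a bond — and the walk stops
the first time the structure's complexity exceeds what is normal for
accessible compounds of its size. The terminal structure is "hard to
synthesize, but only just": complex enough to be implausible, not yet the
degenerate tangle an unbounded walk produces.

## The stop signal

Four structural complexity indices monitor each morph:

* **Bertz**: information content of the bond connectivity (connections
  counted between topological symmetry classes) plus an information term
  for the element distribution.
* **Whitlock**: `4·rings + 2·unsaturations + 1·heteroatoms +
  2·stereocenters`.
* **Barone–Chanon (BC)**: an additive index; this package uses
  `3·degree` per atom, `+3` per heteroatom, `+6` per ring.
* **SMCM-style**: electronegativity-scaled atom contributions
  (Allred–Rochow values relative to carbon), bond contributions
  (order × geometric mean of the atom values), `+2` per ring and `+1` per
  stereocenter.

Because complexity grows with size, raw index values are not comparable
across molecules. Thresholds are therefore calibrated per molecular-weight
bin: the reference library is split into eleven 50-Da bins (0–550 Da,
heavier molecules clamped into the last bin), and per bin and per index
three levels are recorded — the observed maximum, the 999th permille and
the 99th percentile, all by nearest rank (`value at ceil(q·n)`), with no
interpolation. A morph is flagged hard when at least *k* of its four index
values strictly exceed their bin's threshold at the chosen level. The
default stop condition is the 999th permille with *k* = 1, the
best-performing cell of the stop-condition grid experiment
(`stop_condition_grid()` reruns all 3 levels × k ∈ 1..4 = 12
configurations).

Two deliberate conventions:

* **Strict inequality**: a structure *exceeding* the limit is hard;
  sitting exactly at the threshold is not.
* **Nearest-rank percentiles**: "99.9% of the library lies below" is a
  count statement; nearest rank reproduces it without interpolation-mode
  ambiguity, and on the calibration library itself the fraction above the
  99th percentile per index is 1% up to ties.

## The morphing engine

Morphing operates on a hydrogen-suppressed kekulized graph with a simple
valence model (C 4; N 3; O 2; S 2/4/6; P 3/5; halogens 1; charges shift
the allowed counts). Six operator kinds are enumerated exhaustively:

* `ADD_ATOM` — a new alphabet atom single-bonded to any atom with free
  valence; the alphabet defaults to {C, N, O, S, P, F, Cl, Br, I}.
* `REMOVE_ATOM` — any non-cut vertex (the graph must stay connected).
* `MUTATE_ATOM` — an element swap that keeps the bond-order sum feasible.
* `ADD_BOND` — a single bond between two unbonded atoms with free
  valence (always creates a ring).
* `REMOVE_BOND` — ring bonds only.
* `MUTATE_BOND` — a bond-order change within the endpoints' free valence.

A step samples uniformly over the kinds with at least one applicable
instance, then uniformly over the instances of that kind. Every candidate
is valence-valid and connected by construction; sanitization re-checks it,
and a bounded retry (50 attempts) guards the walk against the rare
degenerate draw before declaring a dead end. Paths are capped at 30 steps:
walks that have not crossed the thresholds by then are abandoned
(`EXHAUSTED`) and contribute no hard example. A starting structure already
over the thresholds is reported as a step-0 hit with a warning rather than
silently consumed.

Stereocenters deserve a note: operators never assign stereo labels, yet
stereo-rich skeletons must register as complex, so the Whitlock and SMCM
terms count *potential* tetrahedral centers — four-coordinate carbons with
at most one hydrogen whose neighbor branches fall into pairwise distinct
refinement classes (Morgan-style iterative neighborhood refinement). One
consequence, verified by a property test: adding a substituent can make
two branches identical and *retire* a potential center, so Whitlock is not
monotone under atom addition — any decrease is exactly twice the number of
retired centers. BC, by contrast, is provably non-decreasing under atom
addition.

## Chemistry backends and numerical choices

SMILES parsing, canonicalization and fingerprints are delegated to
OpenBabel. Three consequences are documented rather than hidden:

* **Kekulized graphs.** Aromatic systems are kekulized on input and stay
  kekulized; Bertz symmetry classes use bond-order-weighted (1/order)
  shortest-path profiles compared at 4 decimals. On kekulé-free molecules
  this Bertz implementation agrees with the established reference
  implementation to 1e-6 (frozen goldens in the test suite); on aromatic
  molecules values follow the kekulized orders. Since thresholds are
  calibrated with the same convention that generation uses, the method is
  internally consistent.
* **Fingerprint dialect.** Features are radius-2 circular (ECFP4-class)
  fingerprints folded to 512 bits. Bit positions are backend-specific; the
  backend is recorded in the fingerprint attributes, and only set-level
  properties (Tanimoto similarities, classifier features) are relied on.
* **Index parametrization.** The exact published contribution tables for
  the BC and SMCM indices admit several readings; the parametrizations
  above are fixed, documented and frozen as goldens. Because every index
  enters the method only through library-calibrated percentiles, the
  pipeline is robust to the choice of any monotone-reasonable
  parametrization — absolute threshold values shift, the procedure does
  not.

Other conventions: multi-fragment inputs are reduced to their largest
fragment with charges as parsed (desalting beyond that is out of scope);
molecules failing sanitization are skipped with a warning in bulk readers
and fatal in single-molecule calls; the Tanimoto of two empty fingerprints
is defined as 1.

## Training sets and the benchmark

`build_nonpher_sets()` pairs each threshold-crossing terminal morph with
its own starting structure (strict 1:1 pairing, canonical-SMILES
deduplicated) or, alternatively, with an equal-size random sample from a
reference library. Two competing constructions are provided for
comparison: `build_sascore_sets()` labels precomputed SAscore values
(hard > 6, easy < 4, the band between excluded; SAscore itself is consumed
as an input column, never computed here), and `build_dr_sets()` labels by
chemical-space density (easy ≥ 20 neighbors at Tanimoto ≥ 0.6, hard ≤ 1
neighbor, the middle band kept unlabeled for audit; neighbor counting
excludes the query and runs on the library as given, duplicates included).

The benchmark classifier is a 100-tree random forest on the 512-bit
fingerprints, positive class *easy*, confusion counts at the conventional
0.5 probability threshold, ROC swept over all score thresholds with
trapezoidal AUC (equal to the Mann–Whitney pair probability, ties counting
one half). `repeat_eval()` averages accuracy, sensitivity, specificity and
AUC over five independent easy-class samples; the forest-growth seed is
shared across samples so that degenerate pools (pool size equal to the
hard set) reproduce a single run exactly. Remaining forest hyperparameters
stay at package defaults and are logged in the report manifest.

## The synthetic fixture library

`fixture_library(n, seed)` emulates one property of a vendor catalog — MW
coverage — at desk scale: deterministic combinatorial assemblies of
alkyl/ether/amine/carbonyl/halide/aryl/alicyclic fragments, cycled through
the eleven bins so each is populated. It does **not** emulate a real
catalog's scaffold diversity, functional-group statistics or
complexity-MW correlation structure. Tests built on it therefore
demonstrate that the machinery is correct (calibration ranks, first
crossings, single edits, set construction, classifier plumbing) and that
morphs are separable from their starts; they do not certify classifier
accuracy on real chemistry, which requires calibrating on a real library.

Problem sizes used by the tests and the acceptance script are the
package's chosen desk scale: a 1,100-molecule fixture library (100 per
bin) for calibration and the mini benchmark, 300–500 fresh paths for the
path-contract checks, 150 starts for the stop-condition grid, and
10,000-per-bin synthetic distributions for the calibration oracle.

## Known limitations

* Potential-stereocenter detection uses global refinement classes; rare
  ring pseudo-asymmetry cases can be misclassified. Both counted and
  uncounted conventions appear in practice; the choice is fixed here.
* Kekulization is inherited from the input encoding; two non-isomorphic
  kekulé assignments of the same unsymmetric aromatic ring can differ
  marginally in Bertz. Canonical round-trips are stable in the test suite.
* `REMOVE_ATOM` is restricted to connectivity-preserving deletions rather
  than deletion-with-rerouting; morphing is undirected (no goal structure,
  no tabu list), and duplicate structures may recur within a path —
  deduplication happens at library level.
* The SAscore route consumes precomputed scores; molecules without scores
  cannot enter that comparison.
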