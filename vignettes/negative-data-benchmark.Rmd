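---
title: "Benchmarking negative-data generation for miRNA-target classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking negative-data generation for miRNA-target classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Machine-learning classifiers of miRNA-target interactions (MTIs) are trained
on positive pairs recovered by chimeric-read experiments (CLASH,
CLEAR-CLIP), but no assay captures negative pairs at scale, so every study
manufactures its own negatives. The choice of manufacturing strategy changes
what the classifier learns: a strategy that leaves a systematic fingerprint
in some feature family makes the task artificially easy inside that dataset
and hurts generalization to negatives produced any other way. `mtinegbench`
implements six families of negative-generation methods behind one validity
gate, a fixed 500-feature representation, and an evaluation harness that
measures both intra-dataset performance and how classifiers transfer across
negative datasets.

Because the public datasets behind the original benchmark (CLASH h1-h4,
TarBase, GEO CLIP) require downloads and heavy preprocessing, the package is
exercised end-to-end on a seeded synthetic world that emulates the *shape*
of those inputs. The synthetic results reproduce directional phenomena, not
the real-data numbers.

## The validity scheme

For a miRNA and a target sequence the duplex is the antiparallel base-pair
map (miRNA positions increasing from the 5' end, target positions
decreasing) with its minimum free energy. Seed types follow the standard
definitions: **canonical** requires exact, contiguous Watson-Crick pairing
of one of the miRNA windows 2-7 or 3-8; **non-canonical** additionally
admits G:U pairs and at most one bulged or mismatched nucleotide inside a
window; everything else is **other**. Only canonical and non-canonical
records ("valid") enter any dataset -- positives and negatives alike -- so
negatives cannot be recognized simply by being un-miRNA-like. A second
axis, base-pairing density, counts paired miRNA positions: low (< 11),
medium (11-16), high (> 16); G:U counts toward density (the convention is a
package choice and is stated here because either convention is defensible).
Crossing the two axes yields the six duplex classes used to characterize
datasets.

Defect counting inside a window is made exact as follows: between
consecutive paired window positions with `m` skipped miRNA bases and `t`
skipped target bases, `max(m, t)` defects are charged; unpaired positions at
the window edges each charge one. A window is non-canonical when its total
charge is at most one. This reading resolves the ambiguity of "up to one
bulged or mismatched nucleotide" while agreeing with it on every
unambiguous case.

## Duplex engines

The duplex computation is a pluggable engine. Two engines ship:

* `duplex_engine_dp()` (default) -- a gap-affine antiparallel hybridization
  dynamic program in C++ with a stacking-bonus energy model (G:C -2.2,
  A:U -1.1, G:U -0.6, stacking -1.0, loop open +4.0/extend +1.0, in
  kcal/mol-like units; `N` is unpairable). It is deterministic, supports
  batch scanning of hundreds of thousands of pairs in seconds, and its MFE
  is provably no higher than the energy of any single contiguous helix
  (checked against an exhaustive helix-enumeration oracle in the tests).
* `duplex_engine_rnaduplex()` -- an adapter around the ViennaRNA `RNAduplex`
  binary when it is installed, converting its interstrand dot-bracket
  output into the same pair-map representation.

The DP engine is the default because the benchmark performs on the order of
10^5-10^6 duplex calls (the CLIP Cartesian product alone is ~6 x 10^5) and
an in-process batch path keeps the full run in minutes on one CPU; the
adapter exists for users who want the reference thermodynamics and is
cross-checked in the test suite. All published figures of merit in this
package are computed with the DP engine.

## The synthetic world

`gen_world()` draws, under one integer seed:

* a miRNA catalog (default 300 sequences, 19-24 nt, i.i.d. letters);
* a 3'UTR catalog (default 1,000 sequences, 200-3,000 nt) from a
  first-order Markov chain whose stationary composition hits the requested
  GC fraction (default 0.45) and whose transition bias emulates the
  dominant dinucleotide asymmetries of mammalian 3'UTRs -- CpG depletion
  (bias 0.2) and A/U-run enrichment (1.5, with A<->U at 1.2). The
  dinucleotide structure matters: it is exactly what mononucleotide
  shuffling destroys and dinucleotide shuffling preserves, so without it
  the mono/di contrast the benchmark measures would vanish by construction;
* planted positive interactions (default 2,000): the miRNA is drawn with
  probability proportional to rank^(-1) (a Zipf law, reflecting the
  observation that a minority of miRNAs dominates real interaction sets; the
  exponent is a parameter), and a site reverse-complementary to miRNA
  positions 1-9 is written into a random UTR. Canonical-truth sites are
  fully Watson-Crick; non-canonical-truth sites carry exactly one G:U or
  one mismatch at a uniformly chosen position of 3-7 -- the intersection of
  the two seed windows, so that neither window stays exact and the truth
  label is unambiguous. With probability 0.5 a 4-8 nt helix complementary
  to miRNA positions 13+ is appended after a 3-6 nt spacer, populating the
  medium/high density classes. Fragments are the sites padded to 75 nt;
  coordinates are 0-based half-open on the full mRNA. Planted fragments
  never overlap within a gene, and the catalog the world carries is the
  post-planting one, so site/fragment/mRNA substring closure holds exactly;
* CLIP-style lists (the miRNAs used by the positives; the positive
  fragments plus fragments from 200 genes without planted sites, all >= 40
  nt) and a TarBase-style table (3,000 unique gene-miRNA rows with tissue
  and method annotations, 10% deliberately colliding with planted positives
  to exercise the FPD filter).

The generator does **not** simulate sequencing reads, adapter or alignment
artifacts, expression dynamics, paralogy, or conservation; passing tests
on this world demonstrate correctness of the pipeline's logic and the
reproducibility of directional phenomena, not real-data accuracy levels.

## The six generation methods

All methods compute duplexes through the engine, keep only valid records,
and drop duplicate (miRNA, gene, duplex) triples. A full-positive-dataset
(FPD) built from the positives indexes (gene, miRNA) pairs, (gene,
seed-family) pairs -- seed family meaning identical miRNA positions 2-8, a
package definition since the term is used loosely in the field -- and
positive site spans per gene.

1. **Mock miRNA** -- per positive, mononucleotide-shuffle the miRNA until
   neither seed window matches any catalog miRNA, then re-compute the
   duplex against the full mRNA; retry to validity (cap 100 attempts,
   configurable -- the cap is a package default where the protocol says
   only "a predefined limit").
2. **Mock mRNA** -- three region modes x {mono, di} shuffling: (a) shuffle
   the whole 3'UTR; (b) extend the site 100 nt per side (clipped at the
   bounds), shuffle, trim 50 nt per side, keeping the trimmed flanks as
   feature context; (c) mode (b) plus a Method-1 mock miRNA. Each attempt
   reshuffles. For mode (a) the new site may fall anywhere on the shuffled
   molecule (the protocol is silent; "anywhere" is the package choice).
3. **NPS CLASH** -- mask all positive sites of each (miRNA, gene) pair
   (extended 10 nt per side) with `N`, slide 75-nt windows every 40 nt
   (full windows only; `N` is simply unpairable, so windows overlapping the
   mask are still scanned but can never pair inside it), keep valid window
   duplexes, select one per pair by rule: lowest MFE, random, median MFE
   (even counts take the lower-MFE middle candidate), or random from the
   best 20% by MFE.
4. **TarBase negatives** -- collapse duplicate rows, drop FPD pairs, apply
   the variant filter (all rows / one tissue / microarray method), compute
   the duplex on the full mRNA.
5. **CLIP non CLASH** -- all miRNA x fragment pairs from the CLIP lists,
   minus pairs whose (gene, seed family) is in the FPD; duplex on the
   fragment; discard unpaired miRNA 3' tails longer than 5 nt.
6. **NPS CLIP** -- mask CLIP fragments and FPD sites (+-10 nt) on each CLIP
   mRNA, slide windows as in Method 3, draw a random CLIP miRNA per window
   (retrying to a valid, FPD-clean duplex), select one candidate per mRNA
   by rule.

`combine_negatives()` builds the balanced mixture: equal quotas per dataset,
without replacement, with proportional reallocation (and a warning) when a
dataset is smaller than its quota.

## The 500 features

Five categories with fixed counts -- seed 13, free energy 7, mRNA
composition 62, miRNA pairing 48, site accessibility 370. The exact member
list (`build_schema()`, exportable as JSON) is a package reconstruction
constrained by the category counts and descriptions; any future alignment
to an external feature list is a data change, not a code change. Choices
worth stating:

* *Free energy* includes the duplex MFE, its seed-region (miRNA positions
  <= 8) and 3'-region (>= 9) decomposition under the engine's pair+stacking
  terms, the length-normalized MFE, and self-hybridization proxies of the
  site and its 50-nt flanks as local-structure surrogates.
* *Composition* is mono- and dinucleotide frequencies of the site and both
  50-nt flanks plus site GC and pooled-flank GC; truncated flanks are
  evaluated on what exists, an empty flank contributes zeros (the neutral
  fill).
* *miRNA pairing* caps per-position indicators at position 22; longer
  miRNAs ignore positions beyond it.
* *Accessibility* is the probability that the stretch of width 1-10 ending
  at each of 37 site-relative positions (offsets -10..26 from the site
  start) is entirely unpaired. The engine computes these exactly -- via an
  inside/outside McCaskill-style partition function over a base-pair
  counting energy model (weight 2 per legal pair, minimal hairpin loop 3,
  contributions below 10^-12 pruned) -- on a 120-nt window centered on the
  site. Stretches clipped at the window bounds are evaluated on their
  overlap; positions beyond the molecule contribute the neutral value 1.
  The tests verify the probabilities against brute-force enumeration of all
  secondary structures on short sequences.

The leakage filter removes any negative whose full 500-vector exactly
equals a positive's: classification operates on features, so such a record
is label noise.

## Evaluation protocol

Each negative dataset is undersampled to the positive count and split
80/20, 20 times; repeat `r` uses seed `base_seed + r`, and the positive
partition of a repeat is shared by all datasets. Consequently a fixed
classifier evaluated on different test datasets sees identical positive
rows, and its TPR is constant across test datasets -- the harness exposes
this as a structural invariant rather than an empirical accident. When a
negative dataset is *smaller* than the positive set it is kept in full with
a warning (undersampling positives instead would break the shared-positive
contract).

The binary classifier is gradient-boosted trees (xgboost). A 5-fold
cross-validated grid search (`tune_xgboost()`; grid depth {3,6}, learning
rate {0.05,0.1}, rounds {100,300}) is available; the desk-scale benchmark
runs all datasets at fixed mid-grid values (depth 6, eta 0.1, 150 rounds)
so that a full run stays in minutes. The two-negative-class probe uses the
library defaults deliberately, as a quick separability check.

One-class comparison: a one-class SVM and an isolation forest are trained
on positive training rows only and compared with a binary SVM (sharing the
RBF gamma, default 1/500) and a random forest on identical test sets;
features are standardized with positive-training statistics so the
one-class models never see negative rows even indirectly. The isolation
forest is implemented in the package (standard subsample-and-random-split
trees, path-length anomaly score, threshold 0.5); the one-class SVM's AUC
uses its decision values with inliers positive. The random-forest
counterpart uses `ranger` (100 trees; probability forest).

Statistics: SHAP attributions come from xgboost's TreeSHAP
(`predcontrib`), averaged as absolute values and normalized to sum to one;
two models are compared by a paired Wilcoxon signed-rank test over the
union of their top-100 features, Bonferroni-corrected by the number of
model pairs, reported as -log10(p) with non-significant values shown as 0.
Pairing is by feature (the two normalized importance vectors aligned on the
union), which matches the inputs the comparison is defined on. Note this
pairing is conservative: when both models place a similar total mass on the
union, their paired differences are nearly mass-balanced and the signed-rank
test loses power regardless of how differently that mass is distributed --
on the synthetic world no model pair reaches significance. miRNA
concentration is summarized by the smallest prefix of descending-count
miRNA sequences whose cumulative share *strictly* exceeds 0.9. KL
divergence uses the natural logarithm over the union support of the two
miRNA-sequence distributions, smoothed with an additive pseudocount of 0.5
on the counts (the protocol leaves both the log base and the treatment of
zero-probability source sequences open; both choices are package defaults).

## Numerical and degenerate-input conventions

Coordinates: 1-based positions inside pair maps, 0-based half-open spans
everywhere else. An empty pair list has an unpaired 3' tail equal to the
miRNA length, by convention. Degenerate composition requests (GC fraction 0
or 1), empty catalogs, empty tissue/method vocabularies, k outside {1,2},
and candidates shorter than the seed windows are input errors; a 3'UTR too
short to host a fragment skips the record with a log entry. Ties in the DP
traceback break deterministically (stop, stacked pair, target gap, miRNA
gap), making every duplex byte-stable across runs. All stochastic code
draws from R's RNG (the C++ samplers included), so a single `set.seed()` or
the explicit `seed` arguments reproduce any object bit-for-bit.

## Problem sizes of the shipped runs

The default benchmark (`run_benchmark()`) uses the 2,000-positive world,
two site-level mock datasets (mono/di), 500 features per record, 20
repeats, and the one-class comparison on the dinucleotide dataset; it
completes in roughly 8 minutes on one CPU. The analysis scripts under
`analysis/` run the wider pipeline (all six methods, a seven-dataset
cross matrix, SHAP and two-negative statistics); stages 3-8 together take
tens of minutes at default scale.

## Known limitations

* The synthetic world's negatives are easier or harder than real ones in
  ways that depend on the planted-site model; absolute accuracies are not
  comparable to real-data results, only orderings and invariances are
  meaningful.
* The DP engine's energy model is a simple stacking-bonus scheme, not the
  nearest-neighbor thermodynamic parameters; MFE values are on a
  comparable scale but not interchangeable with ViennaRNA energies.
* The accessibility model counts base pairs instead of stacking free
  energies; its probabilities are exact for its model, not for RNA
  thermodynamics.
* One-class results depend on the novelty-detection hyperparameters (nu,
  gamma); the package reports the matched-hyperparameter comparison, not a
  tuned-for-TNR configuration.
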