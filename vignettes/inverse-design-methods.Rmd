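---
title: "Methods: AI-assisted inverse design of coformer partners"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AI-assisted inverse design of coformer partners}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coformerscout)
```

## The problem

Poorly soluble actives — BCS Class IV flavonoids such as baicalin are the
motivating case — can be reformulated as supramolecular assemblies with a
small hydrophilic partner molecule (a *coformer*) that hydrogen-bonds to
the active and changes its solubility and permeation behaviour. Picking
that partner by trial and error is slow; `coformerscout` implements the
data-driven alternative: learn what makes a partner *suitable* from a
small labeled library, then invert the learned model with a global search
to nominate the best candidate under physicochemical and bioactivity
constraints.

The screen is deliberately small-sample. Its reference use case is a
library of 159 labeled entries split 120/39 for training and held-out
evaluation; a dataset of that size cannot support deep architectures, so
every component is chosen for stability at n of order 100.

## Input features

Each candidate is described by five features:

| feature | units | source |
|---|---|---|
| `mw` | g/mol | computed from structure |
| `hbd` | count of N/O atoms bearing H | computed from structure |
| `tpsa` | Å², Ertl fragment-additive scheme | computed from structure |
| `tyr_inhib` | unitless, scaled to [0, 1] | supplied bioactivity annotation |
| `smiles_enc` | k non-negative counts | computed from structure |

Structure-derived descriptors are computed with OpenBabel (through
ChemmineOB); a bundled table of precomputed values, validated against two
independent toolkits, covers every molecule shipped with the package.
`tyr_inhib` — tyrosinase-inhibitory potential, the bioactivity the screen
wants the partner to contribute — is an experimental annotation and is
never computed from structure. Its [0, 1] scaling is a package
convention: no standard unit exists for such a score.

How a raw SMILES string should enter a numeric classifier is genuinely
open; `encode_smiles()` realizes it as a hashed fragment-count vector:
the molecule is canonicalized, Morgan-style circular atom environments of
radius 0–2 (built from element, degree, attached-hydrogen count and formal
charge) are enumerated, and each fragment identifier is hashed into one of
`k` buckets (default 32). The encoding is deterministic given molecule,
`k` and hash seed, and invariant to how the SMILES was written. This is a
standard small-data featurization, documented as the package's choice
rather than a claim about how any particular study did it.

`featurize_library()` z-scores each column with the sample (n − 1)
standard deviation; constant columns map to zero rather than dividing by
zero. The normalization parameters are stored with the matrix and with
any model trained on it, and are re-applied verbatim to new candidates at
prediction time.

## Feature ranking

`rank_features_rf()` fits a classification random forest (100 trees,
√p features per split, bootstrap resampling — conventional defaults, all
seed-pinned) and reports mean-decrease-impurity importances, normalized to
sum to one and sorted descending with ties broken by input column order.
The forest is a ranking device only: the classifier downstream is trained
on whichever features the analysis keeps (`select_top_features()`).

## The suitability classifier

`train_bp()` trains a feed-forward network — one hidden layer of 16
logistic units and a sigmoid output by default — on mean binary
cross-entropy, with seeded mini-batch stochastic gradient descent
(batch 16, reshuffled each epoch) plus momentum 0.9 at learning rate
0.05. Gradients come from exact error back-propagation
(`bp_loss_grad()`), and the test suite verifies them against central
finite differences on random small architectures using the norm-ratio
error measure.

Early stopping monitors a loss that is not being optimized directly:
when `val_fraction > 0` (the workflow default is 0.2) a seeded stratified
slice of the training data is held out for monitoring only, and training
halts once that loss has not improved for `patience` epochs (default
100). The returned model is the best snapshot seen, so its monitored loss
is the minimum of the whole trace. With `val_fraction = 0` the training
loss itself is monitored, which disables the regularizing effect but
keeps small benchmarks (for example the separability check) exact.

Predictions threshold the output probability at 0.5; no calibration is
attempted because the screen consumes the probability itself as a fitness
value. `evaluate_bp()` reduces a labeled evaluation to a 2×2 confusion
matrix; accuracy, sensitivity and specificity are reported in percent to
one decimal, rounded half-up, which is how such accuracies are
conventionally printed (34 agreements on a 39-entry evaluation report as
87.2 %).

## The genetic-algorithm search

`run_ga()` maximizes the fitness

> fitness = predicted suitability probability − λ · Σ normalized constraint violations

where the violations are box-bound breaches normalized by each bound's
span (unit span for one-sided bounds) and λ defaults to 1. Penalties
rather than hard rejection keep the signal informative in small
populations; a feasible candidate scores exactly its probability, and the
returned best individual is the best *feasible* one whenever any feasible
individual was evaluated.

The engine is an elitist GA: tournament selection of size 3, elitism 2,
crossover at rate 0.8, per-gene mutation at rate 0.1, population 50,
budget 100 generations. Two chromosome representations cover the two
plausible readings of "search":

* **continuous** — the chromosome is a descriptor vector inside the
  constraint box; blend (BLX-0.5) crossover, per-gene Gaussian mutation
  with sd equal to 10 % of the gene's span, and clipping repair. A
  continuous optimum is mapped to a real molecule by
  `map_to_candidate()`: nearest pool record by Euclidean distance in the
  model's normalized feature space, ties to the smallest id.
* **discrete** — the chromosome indexes a candidate pool. Because
  one-point crossover on a single integer gene is degenerate, the index
  is represented internally as a fixed-length bit-string (decoded modulo
  the pool size); crossover and mutation then act on bits.

Pool indices carry no fitness structure, so a discrete search succeeds
exactly when it *evaluates* the optimum at least once. The engine
therefore applies a finite-pool diversity policy (`unique_genotypes`,
default on): a child decoding to a candidate already scored earlier in
the run is replaced by a fresh uniform chromosome, one resampling pass
per generation, elites exempt. This spends the fixed evaluation budget
on unseen candidates instead of re-scoring clones of the incumbent — the
discrete analogue of caching an expensive fitness — and is what makes
exhaustive-search-level recovery on 1000-candidate pools attainable
within 100 generations. It is ignored in continuous mode, where exact
duplicates have probability zero.

Best-ever fitness is recorded per generation (non-decreasing by
construction, which the tests assert for every seed).
`detect_convergence()` defines convergence as the first generation
opening a window (default 10 generations) in which best fitness varies by
at most a tolerance (default 1e-4). This plateau definition is a package
definition; reported convergence generations depend on it and on the
fitness landscape, and on easy synthetic pools the plateau can begin at
generation 0.

## Synthetic study conditions

No labeled coformer library of the reference kind is publicly deposited,
so `generate_library()` supplies the study conditions: n = 159 records by
default, descriptors drawn uniformly over a small hydrophilic chemical
space (mw 75–400 g/mol, hbd 0–6, tpsa 0–150 Å², `tyr_inhib` uniform on
[0, 1], values reported at realistic precision), a 45 % class balance hit
by per-class rejection sampling, and labels from a planted axis-aligned
rule — suitable iff hbd ∈ [1, 4], tpsa ∈ [20, 90] Å², mw ≤ 250 g/mol and
`tyr_inhib` ≥ 0.5, closed bounds to avoid measure-zero ambiguity —
flipped independently at a 10 % noise rate. Each record carries a real
SMILES string from a bundled pool of 177 named small molecules so the
encoding pipeline runs hermetically; for generated records the
descriptors are the sampled values (`descriptor_source = "supplied"`),
not recomputed from that structure. The class balance and noise rate are
package choices where the reference conditions are silent: balanced-ish
classes keep a 120-entry training set usable, and 10 % label noise
represents the irreducible disagreement expected of an experimental
suitability call.

`generate_candidate_pool()` builds the search space: unlabeled candidates
with exactly one planted optimum whose descriptors mirror tranexamic acid
(mw 157.21, hbd 2, tpsa 63.32 — toolkit-computed values — with
`tyr_inhib` 0.95) and whose rule score strictly exceeds every other
candidate's by a configured margin (default 0.05), enforced by rejection
resampling. The optimum's id is recorded in the pool metadata, making
optimizer-recovery tests exact.

What the generator does *not* emulate: correlated descriptors (real
chemical space is far from a product of uniforms), structure–descriptor
consistency for generated records, assay-specific label definitions, and
any relationship between the SMILES encoding and the planted rule (the
rule is a function of the four numeric descriptors only). Passing tests
therefore demonstrate that the pipeline recovers a known signal under
controlled conditions — not that any particular accuracy transfers to
real libraries.

## Assay formulas

`cumulative_permeation()` implements Franz-cell bookkeeping. Sampling
replaces each withdrawn aliquot (volume S, default 1 mL — the usual
protocol volume; the receiver volume has no universal value and is a
required input) with fresh medium, so the cumulative amount permeated per
unit area up to sampling n is

> Q_s(n) = C_sn · V_s / A_s + Σ_{i<n} C_si · S / A_s,

the correction sum restoring the analyte mass already removed. The test
suite checks this against an independent mass-balance simulator to
floating-point accuracy, along with monotonicity and exact 1/A_s scaling.

`viability()` is the CCK-8 ratio 100 · (A_sample − A_blank) /
(A_control − A_blank); values outside [0, 100] are reported with a
warning, never clipped, because they are raw assay signal.
`estimate_ic()` finds IC10/IC50 as the concentration where viability
crosses 100 − level percent: an exactly tested concentration is returned
as-is, otherwise the first bracketing pair crossing from above is
interpolated linearly in log10 concentration (dose series are
conventionally geometric; a linear mode is exposed). A target that is
never bracketed is an error, not an extrapolation.

## Reproducibility and problem sizes

Every stochastic step takes an integer seed: library generation, splits,
forest, network initialization and batch order, and the GA. The workflow
(`run_workflow()`) fans a single global seed out to stages by hashing the
stage name, writes one artifact per stage stamped with the config hash
and seed, and reproduces artifacts byte for byte on re-run.

The test suite exercises the learnability property at n = 1000 with noise
0 (where the planted rule is comfortably recoverable), the separability
benchmark at n = 200 within 500 epochs, forest ranking at n = 200 over 20
seeds, GA recovery on 1000-candidate pools over 20 seeds against an
exhaustive-search oracle, and the permeation identity on 100 randomized
simulated experiments. These sizes were chosen so each property is
comfortably inside its asymptotic regime while the whole suite stays
fast.

## Known limitations

* The 120/39 stratified split is the package default; whether the
  reference split was stratified is unknown, and a `stratified = FALSE`
  mode is provided without asserting either as authoritative.
* Descriptor computation covers MW, HBD and TPSA only; no logP,
  3-D or conformer-dependent descriptors.
* The classifier reports plain accuracy at threshold 0.5; no calibration,
  class weighting, or uncertainty quantification.
* The GA is single-objective; multi-objective trade-offs (for example
  solubility against bioactivity) are out of scope.
* IC estimation interpolates; it does not fit a four-parameter logistic,
  so it needs the target inhibition to be bracketed by observations.

## A minimal run

```{r example, eval = FALSE}
cfg <- workflow_config(seed = 7)
res <- run_workflow(cfg, "screen_out")
glance(res$confusion)     # held-out confusion summary
res$ga$best_candidate     # the nominated coformer
autoplot(res$ga)          # fitness trace with convergence marker
```
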