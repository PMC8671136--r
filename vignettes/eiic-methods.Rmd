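---
title: "Extended invariant information clustering for multi-site functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extended invariant information clustering for multi-site functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Classifiers trained on resting-state functional connectivity (RSFC) pooled
from many acquisition sites tend to collapse when evaluated on a site they
never saw: scanner vendor, repetition time and cohort composition all shift
the feature distribution.  Leave-one-site-out cross-validation (LOSO-CV) —
holding out each site in turn as the test set — is the honest way to measure
that generalization, and it is exactly the regime where naive models fail.

`eiic` implements extended invariant information clustering (EIIC), a
two-phase deep-learning procedure for this regime, together with the full
LOSO-CV evaluation harness and a seeded multi-site simulator, so that the
whole pipeline can be exercised end to end on synthetic data.

## Features

Each subject arrives as a T x R matrix of ROI-averaged BOLD time courses
(for the 110-region Harvard–Oxford atlas, R = 110).  The pipeline computes
the R x R Pearson correlation matrix, applies the Fisher z-transformation
`z = atanh(r)`, and keeps the strictly-lower-triangular entries in row-major
order, giving `R(R-1)/2` features per subject — 5,995 when R = 110.
Numerical choices:

* correlations are clipped to `|r| <= 1 - 1e-7` before `atanh`, so
  degenerate edges stay finite; the unit diagonal never enters the feature
  vector;
* subjects with any non-finite feature (typically a constant ROI time
  course) are removed by `screenSubjects()`; sites left with fewer than
  `min_site_size = 2` subjects are no longer eligible as LOSO test sites,
  though their remaining subjects still contribute to training;
* features are standardized per feature with the mean and standard
  deviation of the *training* subjects only; constant training features map
  to 0.

## The contrastive objective

A softmax output \(\Phi(x)\) is read as a distribution over class
assignments.  For a batch of n labeled pairs \((x_i, x_i')\) the empirical
joint assignment is

\[ P = \frac{1}{n}\sum_{i=1}^n \Phi(x_i)\,\Phi(x_i')^{\mathsf T}, \]

a C x C matrix whose row and column sums are the marginals \(P_c\),
\(P_{c'}\).  The λ-weighted mutual information

\[ I_\lambda(z, z') = \sum_{c,c'} P_{cc'} \ln\frac{P_{cc'}}{P_c^{\lambda} P_{c'}^{\lambda}}
   = I_1(z,z') + (\lambda - 1)\,(H(z) + H(z')) \]

up-weights the marginal entropies, discouraging the degenerate solution
that assigns every input to one cluster.  The IIC loss is
\(-I_\lambda / \ln C\): information maximization becomes loss minimization,
and dividing by each head's own \(\ln C\) makes losses commensurate across
heads.  The default is λ = 5.

With labels available, labeled pairing replaces data augmentation:

* pairs with the *same* label contribute the IIC loss at the two-class main
  head **and** at the overclustering head;
* pairs with *different* labels contribute the IIC loss at the main head
  only, with the second member's output complemented (`1 - Φ(x)` is the
  distribution of the opposite assignment — a two-class construction, which
  is why different-label pairs cannot feed the overclustering head).

Design choices where the formulation is open:

* the empirical joint is symmetrized, `(P + Pᵀ)/2`, and renormalized
  (exposed as a flag); mutual information of an asymmetric empirical joint
  behaves badly;
* every logarithm is stabilized with `eps = 1e-12`, so empty cells cannot
  produce `-Inf`;
* the overclustering width defaults to `c_oc = 10`; it is an auxiliary
  noise-absorbing head and the exact width is not critical.

## Network and training

The trunk is four blocks of fully-connected + batch-normalization + ReLU;
each of the three heads (`iic`, 2 classes; `iic_oc`, `c_oc` classes;
`classifier`, 2 classes) is a single linear-softmax layer off the shared
trunk.  Default widths are `c(1024, 512, 256, 128)` for 5,995-dimensional
input and `c(32, 32, 16, 16)` in the scaled-down analyses below.  Batch
normalization in training mode needs a batch of at least 2 (enforced);
evaluation mode uses running statistics and is deterministic.

**Phase 1 — contrastive prior learning.**  The pool of all unordered
training-subject pairs is reshuffled each epoch and consumed in mini-batches
of `batch_size` *pairs*; an epoch ends when a full mini-batch can no longer
be extracted (the partial remainder is discarded), so iterations per epoch
are exactly `floor(pool/batch)`.  Mini-batches are counted in pairs because
the studied full-scale batch sizes (500, 3,000, 5,000) exceed realistic
subject counts and are only coherent against the quadratically larger pair
pool.  Adam updates the trunk and both IIC heads; the classifier head
receives no gradient in this phase.  After each epoch the pair loss is
evaluated (in evaluation mode) on a fixed, seeded validation pair set —
fixed so the early-stopping criterion is comparable across epochs — and
training stops once it has not improved for `patience` epochs.  The
parameters *and* normalization buffers of the best epoch are returned.

**Phase 2 — transfer learning.**  `freezeTrunk()` marks everything except
the classifier head's linear map as non-trainable, including the
batch-normalization running statistics; the trunk therefore runs in
evaluation mode throughout.  The head is fitted with mean cross entropy
`-ln(Φ(x)[y])` over subject mini-batches, with the same early-stopping rule
on validation cross entropy (the only loss present in this phase).  A
separate `transfer_max_epochs` cap (default equal to `max_epochs`) exists
because at small n a transfer epoch is a single cheap head-only update, so
the phase often needs a larger epoch budget than the expensive prior phase.

The learning rate defaults to 1e-4 (Adam defaults otherwise); the
scaled-down analyses use 1e-3 to 3e-3, matching their much smaller networks.
A practical note on the objective: with λ = 5 the uniform-output saddle
(loss −8 per head term) is a strong attractor, and escaping it requires a
substantial number of updates — which is why the scaled-down configurations
use smaller batches (more updates per epoch, a batch:pool ratio closer to
the full-scale setting) and generous patience.

## LOSO-CV protocol

For every eligible test site: all other sites form the modeling set, which
is split into five folds stratified by (site x class) cell — members of each
cell are shuffled and dealt round-robin with the deal pointer carried across
cells, so each fold tracks the overall site and class composition.  Each
fold serves once as the validation set; a standardizer and a fresh network
are fitted on the remaining four folds and trained through both phases,
yielding five models.  At test time each member standardizes the held-out
site's features with its own training statistics and evaluates its
classifier head; the five two-node outputs are averaged and the predicted
category is the rounded mean score of class 1 (a mean of exactly 0.5
predicts class 1 — a documented tie-break).  Per-site accuracy is tested
against 50% chance with an exact two-sided binomial test (two-sided as the
conservative choice), flagged at p < 0.01.

One master seed fans out to per-site, per-fold and per-epoch streams, so
reports are reproducible end to end and any fold can be re-run
independently.  A leakage guard asserts that no test subject enters any
modeling fold.

Two ablations are provided for comparison.  `ablation = "no-prior"` removes
*only* the prior phase: the randomly initialized trunk is frozen and the
classifier head is trained exactly as in phase 2.  This is the controlled
ablation used in the harmonization analysis, since it isolates the
contribution of contrastive prior learning while holding everything else
fixed.  `ablation = "supervised"` instead trains the whole network end to
end with cross entropy; it answers a different question (two-phase training
vs unconstrained supervised fitting) and is reported alongside the
controlled gap by `scripts/acceptance.R`.  On this simulator's fully
labeled, linearly separable class effects, unconstrained end-to-end fitting
is a very strong baseline; the reported supervised gap makes that visible
rather than hiding it.

## The synthetic generator

`simulateDataset()` emulates the statistical structure the method must
overcome.  A shared base correlation matrix (random factor structure) is
drawn once; on the Fisher-z scale each class-1 subject receives `effect_size`
(default 0.6) on a seeded random `effect_edges` fraction of edges (default
20%), and every subject receives its site's `mean_shift` on all edges — site
effects live on the z scale because that is where the pipeline operates.
The perturbed matrix is back-transformed and projected to the nearest valid
correlation matrix (eigenvalues clipped at 1e-6, rescaled to unit
diagonal).  Time series are then drawn from a stationary vector AR(1)
process whose instantaneous covariance is the target — `ar_coeff` is a
controllable stand-in for repetition-time/temporal-resolution differences —
with optional additive white measurement noise (`noise_scale`) that
attenuates observed correlations.  `t_points` controls sampling noise in the
empirical correlations.

What it does *not* emulate: head motion, global signal artifacts,
age-related connectivity gradients, non-Gaussian BOLD dynamics, atlas
misregistration.  Passing tests therefore demonstrate the machinery and its
contracts, not clinical performance.

`writeFixture()` / `readFixture()` round-trip the records through the
plain-text formats the readers consume (whitespace-delimited `.1D`-style
time series with `#` headers; a phenotype CSV in the ABIDE diagnosis coding
1 = ASD, 2 = TC).

## Problem sizes used in the packaged analyses

The packaged tests and `scripts/acceptance.R` run everything at reduced
scale, chosen as the smallest sizes at which each phenomenon is stable:

* 20 ROIs (190 features), trunk `c(32, 32, 16, 16)`, `c_oc = 10`;
* signal recovery: 4 sites x 50 subjects, class effect 0.6 on 20% of
  edges, no site effects, T = 200; batch 500 pairs, lr 3e-3, patience 10,
  prior cap 40 epochs, transfer cap 300; the same dataset with permuted
  labels calibrates chance;
* harmonization: `confoundedSimSpec()` — 4 sites x 24 subjects, class
  effect 0.5, site shifts of +/-0.4 on all edges with ASD prevalence 0.75 or
  0.25 arranged so the shift-prevalence association is *inconsistent*
  across sites.  A model that uses the site shift as a shortcut is then
  actively misled on held-out sites, which is the failure mode
  harmonization must prevent.  Batch 100 pairs, lr 1e-3, patience 20, prior
  cap 100 epochs, averaged over 5 seeds.

## Known limitations

* The optimizer, network and losses are implemented directly in R matrix
  code; they are exact (gradients are finite-difference checked in the test
  suite) but not tuned for GPU-scale problems.
* The IIC objective's uniform-output saddle makes prior learning sensitive
  to initialization and optimization budget at small sample sizes; the
  transfer phase is considerably more forgiving than main-head cluster
  alignment.
* Different-label pairs only inform the two-class main head; how to extend
  the complement construction to the overclustering head is an open
  question of the method itself.
* The binomial test treats subjects as exchangeable Bernoulli trials; it
  ignores any within-site correlation structure.
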