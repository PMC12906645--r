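---
title: "Gradient-based weight optimization for soft-voting ensembles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gradient-based weight optimization for soft-voting ensembles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbwoem)
```

## The model

A soft-voting ensemble combines the positive-class probabilities
$\hat Y^{(1)}, \dots, \hat Y^{(n)}$ of $n$ base classifiers into a single
prediction

$$\hat y_j \;=\; \mathrm{clip}_{[0,1]}\Big(\sum_{i=1}^{n} w_i\, p_{ij}\Big),$$

where $p_{ij}$ is model $i$'s probability for instance $j$ and
$W = (w_1, \dots, w_n)$ are real-valued weights. Instead of fixing the
weights a priori (plain averaging) or fitting a meta-learner (stacking),
the weights are treated as free parameters and fitted by gradient descent,
monitored by an $\varepsilon$-stabilized binary cross-entropy on a held-out
validation part:

$$\mathcal{L}(W) \;=\; -\frac{1}{N}\sum_{j=1}^{N}\Big[y_j \log(\hat y_j + \varepsilon) + (1-y_j)\log(1-\hat y_j+\varepsilon)\Big],
\qquad \varepsilon = 10^{-10}.$$

The $\varepsilon$ guards the logarithms when an aggregated probability hits
exactly 0 or 1, which is routine once tree-based base models emit hard 0/1
probabilities.

Two initialization variants exist: **uniform** sets every weight to $1/n$;
**random** draws $n$ values uniformly on $[0,1)$ and divides by their sum.
Both start on the probability simplex, but the descent never re-normalizes:
the fitted weights are unconstrained reals, and pair sums above 1 are
normal for well-performing ensembles. Clipping the aggregate to $[0,1]$
before the loss is what keeps the objective defined under unconstrained
weights. The package defaults to uniform initialization because it is
parameter-free and deterministic; the random variant is selected with
`weight_init = "random"`.

## The update direction

The update applied at every iteration is

$$\nabla L \;=\; \frac{1}{N}\, P\,(\hat y - y), \qquad
w \leftarrow w - \alpha\, \nabla L,$$

with $P$ the models-by-instances probability matrix. This direction is the
*exact* gradient of the mean-squared-error surrogate
$\tfrac{1}{2N}\sum_j(\hat y_j - y_j)^2$, not of the cross-entropy above —
the cross-entropy gradient would divide the residual by
$\hat y(1-\hat y)$. The two objectives share their global minimizer in the
realizable case and the MSE direction is a descent direction for both under
small steps, so the combination "monitor cross-entropy, step along the MSE
gradient" behaves like a damped cross-entropy descent. The package
implements the MSE direction as the default (`gradient = "surrogate"`) and
exposes the exact cross-entropy gradient as `gradient = "bce"` for users
who want the textbook pairing. The finite-difference test in the suite
pins the default direction to the surrogate objective at $10^{-6}$.

A related subtlety: the monitored loss as sometimes written without its
leading minus sign would be nonpositive and *minimizing* it would reward
wrong predictions; the package uses the conventional negated form
throughout.

## Early stopping and best-weight restoration

Each iteration first aggregates with the *current* weights and records the
training and validation losses, then updates. A strict improvement of the
validation loss resets the patience counter and snapshots the weights; any
non-improving iteration (including ties) increments it, and the loop breaks
once the counter reaches `patience`. The returned weights are the snapshot
at the best validation iteration — never the post-update weights of the
final iteration — so re-aggregating with the returned weights reproduces
`best_loss` to machine precision, which the suite asserts at $10^{-12}$.

Defaults: `learning_rate = 0.01`, `num_iterations = 1000`,
`patience = 10`. None of these is critical for the library's correctness
properties; they trade optimization quality against runtime and are plain
arguments on `gbwoem_config()`.

## Base models and tuning

The five base families — logistic regression (`stats::glm`), decision tree
(`rpart`), random forest (`randomForest`), k-nearest neighbours
(`class::knn`), and a single-hidden-layer perceptron (`nnet`) — sit behind
one contract: fit on a numeric table, emit probabilities in $[0,1]$. Their
internals are delegated to those established implementations; the package's
own computation starts at the weight optimizer.

Each family is tuned by exhaustive grid search under stratified k-fold
cross-validation (default $k = 5$), scored by mean held-fold accuracy at
the 0.5 threshold, ties broken by grid order. The shipped default grids are
deliberately modest — tree depth 3/5/10, forest size 100/200, $k \in
\{3,5,7\}$ neighbours, hidden width 4/8 — because grids are experiment
configuration, not method; all are replaceable per family. Logistic
regression's default "grid" is the single unpenalized fit: it has no
natural small discrete knob, and a penalized variant would constrain the
feature count without changing any property the package tests. k-NN
probabilities are vote fractions and therefore coarse; that is inherent to
the family, not an artifact.

## Combination search

All subsets of the tuned families of size $\ge 2$ are enumerated in
lexicographic-by-index order ($\sum_{k=2}^{5}\binom{5}{k} = 26$ subsets for
five families). Each subset's weights are optimized from its own
deterministic seed (`config$seed + subset index`), then scored on the
validation and test parts. The winner is the subset with the highest
accuracy on the **selection split**, ties broken by higher AUC, then by
smaller subset, then by enumeration order.

Selecting on the validation part is the default because selecting on the
test part reuses it and optimistically biases the reported test metrics.
`selection = "test"` is provided for protocol comparison, and every report
labels which split selected the winner.

## Preprocessing

All statistics are fitted on the training part only and applied to all
three parts — the leakage-free choice, made deliberately where a protocol
might be silent:

* **Invalid zeros** (physiologically impossible zero entries): replaced by
  the median (default) or minimum of the column's non-zero values; the
  caller names the affected columns, since which zeros are invalid is
  domain knowledge.
* **Categoricals**: one-hot with the training vocabulary; unseen test
  categories map to all-zero indicators.
* **Missing values**: training median (numeric) or mode (categorical).
* **Scaling**: min–max to $[0,1]$ on training min/max; constant training
  columns map to 0; out-of-range test values are clipped.
* **Splitting**: stratified 60/20/20 by largest-remainder apportionment per
  class, so class counts are exact, every part holds both classes, and the
  positive fraction of each part is within 2 percentage points of the
  whole.

The classification threshold is 0.5 throughout, with `>=` mapping to the
positive class.

## The synthetic-data generator

`generate_table()` draws seeded tables that emulate the statistical shape
of imbalanced clinical registries: an exact positive count
(`round(n * positive_fraction)`, so an 8.2% minority regime is hit exactly
at small n), numeric features that are class-conditionally Gaussian with a
mean shift of `class_separation` within-class standard deviations,
three-level categorical features whose level probabilities tilt with class,
and label noise flipping an exact fraction of labels after the features are
drawn. `corrupt_table()` then injects invalid zeros into designated columns
and blanks random cells, emulating the data-quality problems the
preprocessing verbs exist for.

Defaults (chosen once): $n = 768$, 8 numeric + 2 categorical features,
34.9% positives, separation 0.8, 2% label noise — a mid-sized
diabetes-registry regime with moderate, learnable signal.

What the generator does *not* emulate: correlated feature blocks, feature
semantics (a glucose column behaves like any other Gaussian column),
heavy-tailed or multimodal measurement distributions, and
missing-not-at-random patterns. Tests that pass on these tables therefore
demonstrate the pipeline's correctness and determinism, not clinical-grade
performance on real registries.

## Numerical choices and degenerate inputs

* Aggregated probabilities are clipped to $[0,1]$ before the loss and
  before thresholding.
* `bce_loss` is finite for probabilities exactly 0 or 1 by construction;
  $-\log \varepsilon \approx 23.026$ bounds any single-instance
  contribution.
* Precision is defined as 0 (and flagged) when there are no predicted
  positives; recall likewise with no true positives; F1 is 0 when both
  vanish.
* The ROC curve steps once per distinct score (ties share a step), is
  anchored at (0,0) and (1,1), and is integrated by the trapezoidal rule,
  which makes it exactly the pairwise-concordance statistic with ties
  counted one half.
* AUC on single-class inputs, splits that cannot give every part one
  instance of each class, and all-zero columns under zero-imputation are
  signalled, not silently patched (the last leaves the column unmodified
  with a warning).
* A zero iteration budget returns the initial weights with an empty trace.

## Problem sizes used by the checks

The test suite and the acceptance script exercise: 100 random instances
(up to 5 models × 50 instances) for the finite-difference gradient oracle;
200 random instances for the AUC–concordance equivalence; 20 seeded runs of
the oracle/anti-oracle weight-recovery simulation at $n = 80$; and a full
five-family, 26-subset pipeline on a 1,000-instance synthetic table, run
twice to confirm byte-identical artifacts. These sizes make every check
exact or near-exact while keeping a complete run in well under a minute.

## Known limitations

* The surrogate update is not the gradient of the monitored loss; with
  large learning rates the monitored cross-entropy can transiently rise
  even while the surrogate falls. Early stopping on the validation loss is
  the guard.
* Unconstrained weights mean the aggregate relies on clipping; heavily
  clipped regions have zero surrogate gradient for the affected instances.
* No momentum, adaptive learning rates, or simplex-projected descent —
  deliberately out of scope.
* The exhaustive subset search is exponential in the number of families;
  it is intended for the five-family setting (26 fits), not for large model
  pools.
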