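---
title: "Selecting small gene subsets with an enhanced binary particle swarm"
author: "epso package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting small gene subsets with an enhanced binary particle swarm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epso)
```

## The problem

Expression profiling yields matrices with thousands of genes measured on a
few dozen samples. For classifying samples into disease classes, almost all
of those genes are irrelevant or redundant, and a clinically useful
classifier should rest on as few genes as possible. Wrapper feature
selection searches the space of gene subsets guided by the cross-validated
accuracy of a classifier trained on each candidate subset. With $n$ genes
the search space has $2^n$ subsets, so a stochastic search heuristic is
needed; this package uses binary particle swarm optimization (PSO).

A candidate subset is a bit vector $X_i = (x_i^1, \dots, x_i^n)$,
$x_i^d \in \{0, 1\}$: bit $d$ set means gene $d$ is in the subset. A swarm
of $m$ particles moves through this space; each particle remembers the best
position it has visited (*pbest*) and the swarm shares the best position
found by anyone (*gbest*).

## The baseline: conventional binary PSO

Each particle carries a real-valued velocity vector $V_i$, updated per
dimension as

$$v_i^d \leftarrow w\,v_i^d + c_1 r_1^d\,(pbest_i^d - x_i^d)
  + c_2 r_2^d\,(gbest^d - x_i^d),$$

with acceleration constants $c_1 = c_2 = 2$, fresh uniform draws
$r_1^d, r_2^d \sim U[0,1]$ per dimension, and components clamped to
$[-V_{max}, V_{max}]$ with $V_{max} = n/3$. The bit update pushes each
velocity component through the logistic transfer function
$\mathrm{Sig}(v) = 1/(1+e^{-v})$ and sets
$x_i^d = 1$ iff $\mathrm{Sig}(v_i^d) > r_3^d$.

Since $\mathrm{Sig}(0) = 0.5$, a particle with no velocity information
selects every gene with probability one half, and in high dimension the
selected-subset size hovers around $n/2$. That is the baseline's
characteristic weakness: it reduces thousands of genes to about half of
them, not to a compact subset.

## The enhancement: scalar speed and a capped selection probability

The enhanced optimizer (EPSO) makes three coupled changes.

1. **Scalar particle speed.** The velocity vector is replaced by one
   non-negative scalar $s_i$ per particle — conceptually the magnitude of
   the particle's motion. It is updated from bit-vector distances rather
   than per-dimension differences:
   $$s_i \leftarrow w\,s_i + c_1 r_1\,\mathrm{dist}(Pbest_i - X_i)
     + c_2 r_2\,\mathrm{dist}(Gbest - X_i),$$
   with one draw of $r_1, r_2$ per particle per iteration, and the result
   clamped to $[0, V_{max}]$.

2. **Bit-vector distance.** For two positions the elementwise difference
   takes values in $\{-1, 0, +1\}$; with $a$ the number of $+1$ entries
   (genes the best position has and the particle lacks) and $b$ the number
   of $-1$ entries (genes the particle selects needlessly), the distance is
   $|a - b|$. It is non-negative and zero for identical positions. It is
   deliberately not a metric: distinct positions with $a = b$ have distance
   0, and the triangle inequality can fail; only non-negativity and
   definiteness are relied on (and asserted in the tests).

3. **Steepened, inverted transfer.** The transfer function is
   $\mathrm{Sig}(\alpha s) = 1/(1+e^{-\alpha s})$ with slope $\alpha = 5$,
   and the bit rule is inverted: $x_i^d = 0$ iff
   $\mathrm{Sig}(\alpha s_i) > r_3^d$, else $1$. Because $s_i \ge 0$
   implies $\mathrm{Sig}(\alpha s_i) \ge 0.5$, every gene is *deselected*
   with probability at least one half — $P(x_i^d = 1) \le 0.5$ always, and
   $P(x_i^d = 1) \approx 0.0067$ already at $s_i = 1$. This is the
   mechanism that concentrates the search on small subsets.

The slope $\alpha$ is configurable (`sigmoid_steepness`); the default 5
reproduces the reference transfer probabilities exactly
(`modified_sigmoid(1)` $= 0.993307$, `modified_sigmoid(2)` $= 0.999955$ to
six decimals).

## Fitness

A subset $X_i$ with $R(X_i) \ge 1$ selected genes is scored as

$$\mathrm{fitness}(X_i) = w_1 A(X_i) + w_2 \frac{n - R(X_i)}{n},$$

where $A(X_i) \in [0,1]$ is the leave-one-out cross-validated (LOOCV)
accuracy of a support vector machine trained on the selected genes:
RBF kernel, cost $C = 1$, kernel width $\gamma = 1/R(X_i)$, one-against-one
multiclass voting. $w_1 = 0.8$, $w_2 = 1 - w_1 = 0.2$ by default
($w_1$ is restricted to $[0.6, 0.9]$: accuracy outranks parsimony). Read
literally at $R = 0$ the formula would award $w_2$ for selecting nothing;
the empty subset therefore receives a fixed fitness of 0
(`empty_subset_fitness`, configurable).

LOOCV is run as an explicit fold loop: train on $N-1$ samples, predict the
held-out one, repeat for all $N$. libsvm's built-in cross-validation is
deliberately not used, because its one-against-one vote ties are broken in
the order of an internal random fold permutation, which makes its
leave-one-out accuracy irreproducible call to call. A training fold
containing a single class (possible only in degenerate designs such as two
samples with one per class) predicts the only class it has seen. The
classifier is pluggable (`classifier` argument of `loocv_accuracy()`): any
fit/predict pair can stand in for the SVM.

No feature scaling is applied inside the classifier by default; users with
raw intensity data can set `svm_scale = TRUE` or standardize beforehand.

## The optimization loop

Per iteration: evaluate every particle's position, update personal and
global bests, log the iteration, update the inertia weight, then move every
particle. Bests are replaced only on *strict* fitness improvement — on ties
the incumbent stays, since the fitness already penalizes subset size and a
secondary tie-break would double-count it. The budget is a fixed number of
iterations; there is no early stopping and the global best is never reset.

The inertia weight follows the nonlinear recurrence

$$w(t+1) = \bigl(w(t) - 0.4\bigr)\,\frac{T - t}{T} + 0.4,$$

applied once per iteration with the 0-based index $t$ and horizon $T$,
starting from $w(0) = 1.4$. Because the previous value feeds back in, the
decay is much faster than linear: with $T = 50$ the weight passes below 1
around $t = 8$ and is within a few percent of the 0.4 floor by $t = 20$.

Initialization: every bit is an independent fair coin
(`init_bit_prob = 0.5`, matching the transfer function's neutral point),
baseline velocities are uniform on $[-V_{max}, V_{max}]$, and enhanced
speeds are uniform on $(0, 1]$ — strictly positive, and small enough that
the steep transfer does not saturate before the first move.

Reproducibility: a run is a pure function of (dataset, configuration,
seed). The classifier may consume R's random stream internally, so the
fitness evaluator saves and restores `.Random.seed` around each evaluation;
the swarm's own draw sequence is therefore independent of the fitness
path taken (including cache hits — fitness values are memoised per position
within a run).

## Gain-ratio pre-filtering

Before the swarm search, genes are ranked by gain ratio and only the top
$k$ (default 500) are kept, following standard practice for this pipeline;
the fitness' total count $n$ then refers to the reduced set. For a
continuous expression vector the score is computed C4.5-style: candidate
thresholds are midpoints between consecutive distinct sorted values; the
best threshold maximizes the information gain of the induced binary
partition; the score is that gain divided by the partition's own entropy
(split information). Constant genes, zero-gain genes, and all-on-one-side
splits score 0 rather than raising a division error. Ties in the ranking
are broken by original gene order, so results are reproducible. Because
only the ordering of values enters, the score is invariant to monotone
transformations of the expression scale.

## The synthetic data generator

`synthetic_dataset()` emulates the *shape* of benchmark microarray data:
a samples-by-genes Gaussian matrix with a small planted informative subset.
Background genes are $\mathcal{N}(0, \sigma^2)$ i.i.d.; each planted gene
receives a class-dependent mean shift of $c \cdot \delta \cdot \sigma$ for
class index $c = 0, 1, \dots$, with effect size $\delta$ in units of the
noise SD. A single planted gene therefore separates *all* classes once
$\delta$ clearly exceeds 1, and at $\delta = 0$ planted genes are
indistinguishable from background. Classes are balanced up to divisibility
(an explicit `class_weights` argument exposes imbalanced designs).

The defaults — 30 samples, 100 genes, 3 classes, 5 planted genes,
$\delta = 5$ — are the desk-scale study conditions used by the test suite,
chosen so that a laptop run finishes in seconds while the planted subset
is unambiguous. What this generator does *not* emulate: gene–gene
correlation, heteroscedastic or log-normal intensity distributions, batch
effects, and missing values. Passing tests on this generator demonstrate
the mechanics of the search and scoring, not performance on real
microarray data.

## Behavior of the enhanced search, and a known limitation

The capped selection probability is a double-edged sword, and it is worth
being explicit about the dynamics so users can interpret results.

The speed recurrence adds non-negative distance terms of order up to $n$
each iteration. As soon as a particle's sampled position becomes sparse
while its personal best is still dense (about $n/2$ genes from fair-coin
initialization), the distance terms jump to order $n/2$, the speed hits the
clamp $V_{max} = n/3$, the transfer saturates at 1, and the particle's
subsequent positions are essentially all-zero — which cannot improve its
personal best, so the state is self-sustaining. In a typical run the whole
swarm passes through exactly this funnel within the first few iterations.

Consequently the search effectively concentrates its useful sparse
sampling in a short early window, plus any particle whose personal best
itself becomes sparse (for such a particle the distance terms stay small,
the speed relaxes, and sparse resampling continues). Two regimes follow:

* If an early sparse sample scores well — easy when most genes in the
  (pre-filtered) pool carry class signal — the global best switches to a
  compact subset and is then refined towards a handful of genes. This is
  the regime in which the method shines, returning subsets of 2–10 genes
  at full LOOCV accuracy.
* If the gene pool is mostly noise (e.g. 5 informative genes in 100), a
  dense random subset already classifies perfectly and sets a high
  incumbent fitness, while early sparse samples rarely contain an
  informative gene. The global best then often stays at a dense position
  of roughly $n/2$ genes for the whole run. The same dichotomy is visible
  in published results for this family of methods: hard many-class
  datasets end near half of the filtered genes, easy ones end with a
  handful.

The per-run probability of escaping to the sparse regime rises with swarm
size and with the informative density of the pool, but on the desk-scale
study conditions above it is far from certain; the acceptance-style tests
that demand a sparse outcome in nearly every run document this expectation
and currently fail for exactly this reason. The dynamics follow from the
update equations themselves; "fixing" them (e.g. re-anchoring personal
bests, or normalizing the distance terms) would change the method, which
this package deliberately does not do.

## Numerical and design choices

* **Transfer slope.** The enhanced transfer is implemented as
  $\mathrm{Sig}(\alpha s)$ with $\alpha$ a parameter (default 5). The
  reference probability values for this function are reproduced only with
  a slope of 5, while its plain algebraic form corresponds to
  $\alpha = 1$; making the slope explicit and configurable resolves that
  ambiguity without hard-coding either reading.
* **Speed clamp.** The velocity clamp for the baseline is symmetric,
  $[-V_{max}, V_{max}]$; a one-sided literal reading with lower bound 1
  would contradict the transfer analysis of negative velocities, so the
  bound is applied to the magnitude. The enhanced speed reuses
  $[0, V_{max}]$: distance terms can reach $n$ per iteration and an
  unbounded speed would saturate the transfer permanently and
  irreversibly.
* **Iteration indexing.** The loop runs $t = 0, \dots, T-1$; the analytic
  endpoint $t = T$ (where the inertia equals the floor exactly) is
  reachable by calling `update_inertia()` directly.
* **Per-run seeds.** `run_repeated()` derives run $r$'s seed as
  master $+\,(r-1)$ and records it, so any row of a report can be
  reproduced as a single run.
* **Empty subsets.** Fitness 0, as above; the accuracy slot of such an
  evaluation is `NA`.
* **Degenerate folds.** Single-class training folds predict that class
  deterministically.

## Problem sizes used by the test suite

The suite runs entirely on generated data: the study conditions above for
end-to-end checks (10 matched-seed pairs of 20-particle, 50-iteration runs,
shared across tests), a few hundred small random instances for the
brute-force oracle comparisons (gain ratio against an all-splits
enumeration at $10^{-12}$; LOOCV against an independently coded fold loop),
and $10^5$-draw Monte-Carlo checks of the bit-update probabilities. The
published full-scale protocol (100 particles, 500 iterations, ten
real microarray datasets) is out of scope here; the package exposes those
values as configuration defaults (`swarm_config()`) for users who want to
run it on real data.
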