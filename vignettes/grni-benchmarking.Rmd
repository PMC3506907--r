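---
title: "Benchmarking gene regulatory network inference with grnibench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking gene regulatory network inference with grnibench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnibench)
options(grnibench.verbose = FALSE)
```

# The problem

A gene regulatory network (GRN) is a directed graph in which transcription
factors (TFs) regulate target genes. Inferring the network from expression
data is a core task of systems biology, and a crowded one: mutual-information
(MI) scores, correlation, partial correlation, tree ensembles and supervised
classifiers all compete, each with tunable parameters that can move accuracy
substantially. `grnibench` packages the whole comparison loop: a generative
simulator with known ground truth, re-implementations of the standard
unsupervised scorers and a supervised per-TF SVM, a tie-aware AUC evaluator
with a parameter-sweep harness, and set-level comparison of
condition-specific networks (including regulator-switch detection).

Everything is seeded; given a seed, every dataset, score matrix and AUC in
the package is bit-reproducible.

# The simulator

## Networks

`generate_source_network()` builds a weakly connected directed network whose
edges all originate at TFs. `mean_degree` is the average total (in + out)
degree, so a network of `n` genes receives `max(n - 1, round(mean_degree *
n / 2))` edges; the floor is what guarantees connectivity, via a random
spanning tree rooted in the TF set. The `"scale_free"` topology grows hubs
by preferential attachment on TF out-degree; `"erdos_renyi"` spreads edges
uniformly. `sample_subnetwork()` grows an induced subgraph by seeded
neighbour addition, which is why sub-networks of a denser source carry more
edges at equal node count — the property that drives the density comparison
below.

## Kinetics

Expression is the steady state of a Hill-kinetics regulation map. Each gene
has a basal level $b_i \in (0,1]$; each edge carries a Hill coefficient
$n$ and half-saturation constant $K$, contributing an activation term
$A(x) = x^n/(K^n + x^n)$ or repression term $R(x) = K^n/(K^n + x^n)$
(both are exactly $1/2$ at $x = K$). An unclamped gene's level is

$$x_i = \min\Big(1,\; m_i b_i \prod_{a \in \text{act}(i)} \big(\ell + (1-\ell) A(x_a)\big) \prod_{r \in \text{rep}(i)} \big(\ell + (1-\ell) R(x_r)\big)\Big)$$

with leak $\ell$ (default 0.1) and per-sample basal multiplier $m_i$. The
fixed point is found by damped synchronous iteration (damping 0.5,
tolerance 1e-8, at most 5000 iterations); damping is what lets feedback
cycles converge, and a non-convergent sample is retried once with lighter
damping (0.2) before the solver gives up and names the genes still moving.
Converged solutions are verified fixed points: reapplying the regulation
map moves them by less than 1e-6.

Default parameter ranges — basal in [0.3, 1], Hill $n$ in [1, 4], $K$ in
[0.2, 0.8] — were chosen once so that typical steady states sit in the
interior of [0, 1] with regulators operating near their half-saturation
points, i.e. where regulation is actually informative. They are sampled
uniformly per gene/edge by `assign_kinetics()`.

## Experiment designs

`simulate_experiment()` mirrors the two benchmark designs that matter for
method comparison:

* **knockdown** — one wild-type sample plus one sample per gene with that
  gene clamped to 0.01; a `g`-gene model always yields `g + 1` samples. The
  clamp is 0.01 rather than 0 so multiplicative noise stays well defined.
* **multifactorial** — every sample perturbs every gene's basal activity by
  a lognormal multiplier $e^{N(0, \tau^2)}$ with $\tau = 0.5$ by default,
  emulating a cohort in which each sample is a genome-wide profile from a
  different individual.

After solving, multiplicative lognormal measurement noise (default
`noise_sigma` 0.05) is applied and values are clipped to [0, 1].

What the generator deliberately does **not** emulate: time courses,
microRNA or chromatin regulation layers, combinatorial (non-multiplicative)
regulation logic, heterogeneous cell populations, and array-specific noise
structure. Passing tests therefore show that a method recovers
Hill-kinetics steady-state structure under these designs — not that it will
reach the same accuracy on clinical microarray data, where every published
comparison finds accuracy substantially lower.

## Planted regulator switches

`make_condition_pair()` copies a kinetic model and, for each switch, moves a
group of targets from one TF to another, keeping the edges' signs and Hill
parameters so the two conditions differ only in wiring. Targets whose sole
regulator is the outgoing TF are preferred, which makes the planted truth
recoverable by per-target regulator comparison (`regulator_switches()`
groups targets by their (old TF, new TF) pair). Multi-regulator targets are
reported separately rather than forced into pairs.

# Mutual-information core

Three discretizers (`equalfreq`, `equalwidth`, `globalequalwidth`; ties in
equal-frequency binning go to the lower bin, the last bin is right-closed)
feed four histogram entropy estimators (in nats):

* `empirical` — plug-in $-\sum \hat p_i \ln \hat p_i$;
* `mm` — Miller–Madow, plug-in $+ (\hat m - 1)/(2n)$ with $\hat m$ the
  occupied bins;
* `shrink` — plug-in on James–Stein probabilities shrunk toward uniform
  $1/m$, with the closed-form intensity clipped to [0, 1];
* `sg` — plug-in on pseudocount probabilities $(n_i + 1/m)/(n + 1)$
  (symmetric Dirichlet prior with concentration $1/m$; the full Bayesian
  posterior average is out of scope).

MI is $H(X) + H(Y) - H(X, Y)$ with the joint histogram spanning the full
$m_x \times m_y$ grid (structural zeros matter for `shrink` and `sg`);
negative corrected estimates are clipped to 0. The canonical sweep grid is
bins 2–10 by 1 and 15–95 by 5 (26 values), crossed with the 4 estimators
and 3 discretizers: 312 configurations per MI-based method. Which
bin-boundary convention other implementations use is rarely documented, so
small AUC differences against them are expected.

# The inference methods

The four MI-family methods read the data only through the MI matrix:
relevance networks (`rn()`, scores = MI), CLR (`clr()`, per-row background
z-scores combined as $\sqrt{z_i^2 + z_j^2}$, zero-variance rows contribute
0), ARACNE (`aracne()`, data-processing-inequality pruning — marks are
computed against the original matrix and applied afterwards, no cascading;
ties survive because the inequality is strict; its edge set is provably
nested in the relevance network's) and MRNET (`mrnet()`,
relevance-minus-redundancy forward selection per target, ties broken by
gene order, direction collapsed by the larger of the two directional
scores).

Correlation-family methods: `correlations()` (absolute Pearson, Spearman or
Kendall; constant genes score 0 rather than NA, so matrices stay finite),
`wgcna()` (soft-threshold adjacency $|r|^\beta$, softpower default 7, with
an optional topological-overlap variant; module detection is not used) and
`pcit()` (first-order partial correlations over every gene trio, the trio
tolerance being the mean of the three |partial/direct| ratios). The PCIT
significance rule has minor published variants; the implemented rule lives
in one function so a variant can be substituted, and — a property worth
knowing — it only removes an indirect chain shortcut when the chain links
are of moderate strength, because a strong chain inflates the tolerance.

`genie()` is the one directed unsupervised method: per target, a random
forest regresses the target on all candidate regulators and the normalized
impurity-reduction importances become edge scores (defaults 1000 trees,
sqrt feature sampling; tests use fewer trees).

## The supervised method

`sirene()` trains one RBF-kernel SVM per TF: genes are instances, the
feature vector is the expression profile, known targets are positives and
all other genes are treated as negatives — the standard assumption, and a
known optimistic-labeling bias. Scores are cross-validated decision values
(3 folds by default, stratified so every training split keeps both
classes), so no gene is ever scored by a model that saw its label. Class
weights are balanced; the kernel width defaults to the inverse median
squared pairwise distance between gene profiles. The regularization
constant defaults to $C = 10$: development runs on simulated multifactorial
data showed that $C = 1$ underfits systematically with balanced class
weights on [0, 1]-scaled profiles, and the package treats the SVM
hyperparameters as open configuration rather than fixed protocol. TFs with
fewer than `min_positives` (default 2) known targets are skipped and
listed.

# Evaluation

`roc_auc()` computes AUC by the midrank rank-sum formula, equivalent to the
fraction of positive–negative pairs ordered correctly with ties counted
one-half; 0.5 is chance, 1 is perfect. The candidate universe is
closed-world over the score matrix's gene pairs: ordered non-self pairs in
directed mode, unordered pairs with the gold standard collapsed by OR in
undirected mode. Symmetric scorers default to undirected evaluation and
directed scorers to directed — each method is evaluated on the claim it can
actually make — and both modes remain available, as do optional
restrictions (candidate regulators, TF–TF pair exclusion, held-out pair
exclusion for supervised evaluation). Ties in best-configuration selection
break by enumeration order.

`parameter_sweep()` enumerates a grid one row per configuration, records
error rows for infeasible configurations instead of aborting, and
`sweep_mi_methods()` shares each MI matrix across the MI-family methods so
a joint sweep costs one matrix per configuration. `compare_methods()` runs
two-sided Mann–Whitney tests on AUC groups with Bonferroni adjustment
(default significance level 0.01).

# Condition-network comparison

`differential_edges()` partitions two networks' positive-weight edge sets
into condition-specific and shared parts with per-edge weight pairs;
`regulator_switches()` detects single-to-single regulator reassignment;
`hub_degrees()` ranks TFs by out-degree; `edge_overlap()` reports the
fraction of a reference network's edges found in a second network
(optionally restricted to the top-k edges by weight; a Jaccard variant sits
behind a flag because "overlap" is not uniquely defined in the literature).

# Validation suite: designs and sizes

The test suite re-derives every operation against independent naive oracles
(brute-force pair counting for AUC, direct joint-histogram summation for
MI, plain-loop re-implementations of CLR/ARACNE/MRNET/PCIT) and runs four
scaled-down end-to-end studies, whose sizes were chosen to make each effect
measurable on a single CPU in minutes:

* **design comparison** — 100-gene scale-free networks, 5 seeds, knockdown
  versus 100-sample multifactorial data, MI methods optimized over a
  reduced grid (all estimators and discretizers, bins {3,4,5,6,8,10});
  compared by the median AUC across RN/CLR/MRNET.
* **supervised versus unsupervised** — 60-gene networks, training on a
  random half of the gold edges, held-out directed AUC against the best of
  five unsupervised scorers, 3 seeds, majority.
* **density effect** — 300-node sources at mean degree 4 versus 7, twelve
  (3 sizes × 4 sample counts) sub-network datasets each, CLR accuracy
  compared by Mann–Whitney direction.
* **switch recovery** — 40-gene networks, two planted switches of five
  targets, noiseless knockdown data, per-target best-regulator reduction of
  correlation scores, precision and recall of recovered (target, old TF,
  new TF) assignments.

# Known limitations

The simulator's steady-state map is multiplicative in its regulators; it
cannot represent XOR-like combinatorial logic. The supervised method's
negative labels are polluted by unknown true targets (in simulation the
gold standard is complete, so the bias only matters on real data).
Kendall-based scoring is exact but slow for thousands of genes. PCIT and
ARACNE are cubic in gene count and written in plain R; they are meant for
the few-hundred-gene networks this package targets, not genome-scale
matrices.
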