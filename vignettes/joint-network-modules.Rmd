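---
title: "Joint modules across subjects: model, optimizer and evaluation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modules across subjects: model, optimizer and evaluation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jsnmf)
```

## The problem

Resting-state functional brain networks assign one weighted graph to each
subject: nodes are regions of interest, edge weights are (non-negative,
thresholded) Pearson correlations of regional activity. Subjects differ in
individual edges, but the modular organization — which regions cluster
together — is assumed shared. This package finds that shared organization
by factorizing all subject networks *jointly*, and then uses the modules
as feature-selection masks for case/control classification.

## The model

Given $n$ symmetric non-negative adjacency matrices
$A^{(1)},\dots,A^{(n)}$ over $N$ common nodes, we minimize

$$
O \;=\; \sum_{v=1}^{n}\bigl\lVert A^{(v)} - H S^{(v)} H^\top \bigr\rVert_F^2
\;+\; 4\alpha \sum_{k=1}^{K} \lVert h_k \rVert_1,
\qquad H \ge 0,\; S^{(v)} \ge 0,
$$

with one shared indicator matrix $H \in \mathbb{R}^{N \times K}$ and a
per-subject $K \times K$ compression matrix $S^{(v)}$ that absorbs how
strongly each subject expresses every module (and module pair). The
$L_1$ penalty on the columns $h_k$ (equal to $4\alpha\,\mathrm{sum}(H)$
since $H$ is non-negative) pushes rows of $H$ toward a single dominant
module.

Setting $\partial O/\partial S^{(v)} = 0$ gives the closed-form update

$$
S^{(v)} = (H^\top H)^{-1} H^\top A^{(v)} H\, (H^\top H)^{-1},
$$

and the Karush–Kuhn–Tucker conditions yield the multiplicative rule

$$
H \leftarrow H \odot
\frac{\sum_v A^{(v)} H S^{(v)}}
     {\sum_v H S^{(v)} H^\top H S^{(v)} + \alpha E},
$$

with $E$ the all-ones $N \times K$ matrix. Putting $\alpha E$ in the
denominator is the standard sparse-SNMF form: it is exactly the
majorization step for the objective above (the penalty gradient is
$4\alpha E$ and the whole rule cancels the common factor of 4), and it
shrinks $H$ as a sparsity penalty must.

After fitting, each column of $H$ is divided by its maximum — so modules
of different sizes compete on equal footing — and node $i$ is assigned to
the module with the largest entry in row $i$ (ties to the smallest
index). The factorization is scale/rotation-reduced, not fully
identified, which is why assignments come from the normalized matrix and
why multiple restarts are compared by adjusted Rand index (ARI).

## Numerical design of the optimizer

Several choices here are the package's own; the model above does not fix
them.

**Initialization and burn-in.** $H$ starts i.i.d. uniform$(0,1)$
(seeded). A uniform positive matrix is nearly rank one: all columns are
strongly positively correlated, so the joint updates start inside a basin
where $HSH^\top$ explains only the global mean structure, and they
rarely escape it. Before the joint alternation, `jsnmf_fit()` therefore
runs a short burn-in (default `burnin = 100` iterations) of damped
symmetric-NMF steps with every $S^{(v)}$ pinned to the identity,
$H \leftarrow H \odot \bigl(\tfrac12 + \tfrac12\,
\sum_v A^{(v)}H \,/\, \sum_v H H^\top H\bigr)$. With $S = I$ the
factorization $A \approx H H^\top$ has no column-mixing freedom, so the
burn-in pulls the columns of $H$ apart toward distinct dense subgraphs;
the joint phase then refines them. On planted-partition benchmarks this
turns near-chance recovery into exact recovery across seeds; the
recorded objective trace starts after the burn-in.

**Monotone trace by construction.** The clipped closed-form $S$ step is
not guaranteed to lower the objective (clipping negative entries can
raise it), and multiplicative steps on quartic symmetric objectives can
overshoot. `jsnmf_fit()` accepts a candidate $S^{(v)}$ only if that
view's fit term does not increase, and geometrically damps the $H$ step
($H \odot (\text{num}/\text{den})^{\gamma}$, halving $\gamma$) when the
plain step would raise the objective. In practice the plain steps almost
always decrease and the safeguards are idle; they exist so the
`objective_trace` invariant (non-increasing within $10^{-9}$) holds for
every input. The exported one-step operations `update_S()` and
`update_H()` remain the plain formulas.

**Other constants.** Every denominator carries `eps = 1e-12` against
0/0; convergence is declared when the relative objective change falls
below `tol = 1e-6` (cap `max_iter = 500`); negative entries produced by
the unconstrained $S$ solve are clipped to 0 (a message reports
clipping beyond $10^{-8}$); a rank-deficient $H^\top H$ falls back to
the Moore–Penrose pseudo-inverse with a warning. One "iteration" is all
$n$ S-updates followed by one H-update, with the objective evaluated
after both.

**Restarts.** `jsnmf_restarts()` refits from `runs` seeds (seed,
seed+1, ...), and `select_representative_run()` keeps the run with the
highest mean ARI against all others — the run most typical of what the
optimizer finds, not the lowest-objective run, matching how a shared
partition should be chosen when the end product is the partition itself.

## Network preprocessing

`preprocess_fbn()` reproduces the conventional correlation-network
filter: negative weights are removed first, then weights below the
threshold (default 0.35, a common cutoff separating reliable
correlations from noise); a weight exactly at the threshold survives.
The filter is idempotent and applied per subject before any averaging,
so the "average network" used for evaluation is the mean of the filtered
views. `is_connected()` reports — rather than repairs — views that the
threshold disconnects; the package deliberately applies one global
threshold instead of adapting it per subject.

## Module-quality indices

With $V_k = \sum_{i \in M_k}\sum_j A_{ij}$ (volume) and
$W_k = \sum_{i,j \in M_k} A_{ij}$ (intra-module weight, both
orientations), and $T = \sum_{ij} A_{ij}$:

* **modularity** $\sum_k (W_k/T - (V_k/T)^2)$ — the weighted
  Newman–Girvan form; the normalization by $T$ makes the index
  dimensionless and comparable across networks (and is the only reading
  under which the three indices live in $[-1,1)$ / $[0,1]$);
* **conductance** (compactness variant) — the mean over non-empty
  modules of $W_k/V_k$, the probability that a one-step random walk
  started in a module stays in it;
* **coverage** $\sum_k W_k / T$ — the intra-module fraction of all
  weight.

Empty modules contribute nothing to modularity and coverage and are
excluded from the conductance mean (with a warning). Both double-sum
conventions count each undirected edge twice, so the factors cancel.
`quality_scan()` reports all three indices per $(K,\alpha)$ cell twice:
averaged over per-view evaluations of the single shared partition, and
evaluated on the average network — the two standard evaluation blocks
for multi-subject clustering.

## Features and classification

`extract_features()` turns each subject's network into the vector of
upper-triangle edge weights, either inside one module ($m$ nodes give
$m(m-1)/2$ features) or over the whole network. Which module corresponds
to an anatomical system of interest (e.g. the default mode network) is
decided by the user: an explicit index, or `match_module_to_reference()`
which maximizes Jaccard overlap with a reference node list.

`loocv_scores()` implements leave-one-out cross-validation: features are
z-scored on the training fold only, the held-out subject is transformed
with the training moments, and for the selection-embedded classifiers
(RFE-SVM, PSO-SVM) feature selection is re-run inside every fold — the
leakage-safe protocol. Seven classifier families are wrapped
(`linear_svm`, `pso_svm`, `rfe_svm`, `random_forest`, `lda`,
`lasso_logistic`, `knn`); their internals are delegated to e1071,
randomForest, MASS, glmnet and class — only the evaluation mathematics
is bespoke.

ROC curves follow two threshold regimes: SVM-family margins are swept
over the observed score range, probability outputs over an even grid on
$[0,1]$ (101 points); both sweeps are bracketed by $\mp\infty$ so the
curve always contains $(0,0)$ and $(1,1)$. A subject is predicted
positive when its score is $\ge$ the threshold; TPR $=$ TP/P,
FPR $=$ FP/N; AUC is the trapezoidal integral of TPR over FPR. On
tie-free scores this equals the Mann–Whitney pairwise statistic exactly,
which the tests verify.

**Selection wrappers.** RFE trains a linear SVM, ranks features by
absolute weight and drops the bottom half per round (step 0.5) until
`n_keep` remain. Binary PSO uses 20 particles and 30 iterations, inertia
decaying 0.9 → 0.4, cognitive = social = 2, sigmoid-Bernoulli position
resampling, fitness = internal 3-fold AUC of a linear SVM; the all-ones
mask is seeded as one particle so the internal criterion can never end
below "use everything", and all-zero masks are repaired by switching one
random feature on. These constants are package defaults chosen from
common PSO practice, not fitted to any dataset.

## What the synthetic generator does and does not emulate

`generate_multiview()` draws, for every view, edge weights
$\mathcal{N}(p_{\text{in}}, \sigma)$ within planted modules and
$\mathcal{N}(p_{\text{out}}, \sigma)$ between them, symmetrizes, clips
to $[0,1]$, zeroes the diagonal and applies the same threshold filter as
real data. `generate_cohort()` adds a case group whose
within-one-module means are shifted by `effect_delta`. Defaults
($p_{\text{in}} = 0.7$, $p_{\text{out}} = 0.2$, $\sigma = 0.05$,
`effect_delta = 0.2`) represent a clearly modular correlation network
with a localized group difference — a strong-signal regime chosen so
that recovery failures indicate optimizer defects, not ambiguous truth.

The generator models correlation *magnitudes* directly; it does not
simulate BOLD time series, spatial autocorrelation, negative
correlations, realistic noise spectra, or inter-subject registration
error. Passing tests therefore demonstrate that the algorithmic chain is
correct and stable under its own assumptions — not that real
resting-state cohorts will separate this cleanly. Out-of-range noise
excursions are clipped, not resampled, which slightly biases edge means
toward the interior of $[0,1]$ at high $\sigma$; at the default
$\sigma = 0.05$ the effect is negligible.

## Problem sizes used by the test suite

The suite exercises the optimizer on random instances with
$N \in \{10, 30\}$, $K \in \{2, 4\}$, $n \in \{1, 3\}$,
$\alpha \in \{0, 1\}$; planted recovery at $N = 60$, $K = 3$, five
views; and the classification comparison on cohorts of $2 \times 20$
subjects over 60 nodes with a 4-module truth. These sizes keep a full
run of the suite in the low minutes on one core while leaving every
quantity far from trivial (the whole-network feature space alone has
1770 dimensions against 39 training subjects). The acceptance script
(`scripts/acceptance.R`) recomputes the headline quantities at exactly
these sizes.

## Known limitations

* The factorization is non-convex; different seeds can find different
  partitions on weakly modular data. The restart + representative-run
  machinery measures this (inter-run ARI) rather than hiding it.
* $K$ is not selected automatically; `quality_scan()` provides the
  evidence (modularity peaking at the planted/true $K$) but the choice
  stays with the user.
* The conductance variant used here rewards compact modules (higher is
  better); it is not the cut-conductance minimized in spectral graph
  theory.
* With $\alpha > 0$ the penalty influences early iterations but decays
  in effect as the scale ambiguity between $H$ and $S^{(v)}$ lets
  $\mathrm{sum}(H)$ shrink; sparsity of the final normalized $H$ comes
  mostly from the data structure itself.
* Leave-one-out evaluation has high variance at cohort sizes typical of
  neuroimaging; AUC differences between feature scopes should be read
  across repeated cohorts (as the acceptance script does), not from a
  single split.
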