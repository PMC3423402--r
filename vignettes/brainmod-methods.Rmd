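---
title: "Methods: community structure and classification of resting-state connectivity networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community structure and classification of resting-state connectivity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(brainmod)
```

brainmod implements a complete analysis chain for resting-state functional
connectivity: from regional BOLD time series to group-level statements about
the community structure of the brain's functional network, and to
single-subject diagnostic classification. This vignette explains the model
behind each stage, the choices that were genuinely open and how we resolved
them, and what the synthetic cohort generator does and does not emulate.

## From time series to connectivity

Each subject contributes a $T \times N$ matrix of regional time courses
($N = 95$ regions, $T = 483$ volumes at TR = 1.25 s in the default study
conditions). Functional connectivity is the zero-lag Pearson correlation of
each pair of regions (`compute_correlation()`), giving a symmetric $N
\times N$ matrix with unit diagonal.

Inter-regional correlations carry a spatially non-specific background: the
correlation of two regions decays roughly logarithmically with the
Euclidean distance between their centroids, because adjacent tissue shares
unspecific signal sources. We remove it per subject by ordinary least
squares of $r_{ij}$ on $\log d_{ij}$ over all unordered pairs
(`fit_distance_trend()`), subtracting the fit
(`apply_distance_penalty()`). The residual matrix is signed, has zero
diagonal, and emphasises coupling that is strong *relative to its spatial
proximity* — homotopic (left–right homologue) pairs and other long-range
connections. Three choices here were open and are deliberately isolated
behind the module interface so they can be swapped:

* distance is Euclidean between region centroids, in mm;
* the fit is per subject (each subject has their own intercept, slope, and
  residual standard deviation, which is also the quantity compared between
  groups by `compare_residual_errors()`);
* raw correlations, not Fisher-z transforms, are regressed — the penalty
  is a descriptive detrending, not an inferential model.

Because the fit is OLS, penalizing a matrix with its own model leaves
residuals with exactly zero mean, and refitting a penalized matrix returns
a null trend (slope and intercept 0 to $10^{-10}$); both properties are
asserted in the tests.

## Community structure on the full signed matrix

Community detection uses an asymmetric *signed* modularity: positive
weights should lie within modules, negative weights should separate them.
With $w^{\pm}$ the positive/negative parts of the matrix, $s^{\pm}$ their
node strengths and $v^{\pm}$ their totals,

$$Q^{*} = \frac{1}{v^{+}}\sum_{ij}\left(w^{+}_{ij} -
\frac{s^{+}_i s^{+}_j}{v^{+}}\right)\delta_{c_i c_j} -
\frac{v^{-}}{v^{+}+v^{-}}\cdot\frac{1}{v^{-}}\sum_{ij}\left(w^{-}_{ij} -
\frac{s^{-}_i s^{-}_j}{v^{-}}\right)\delta_{c_i c_j},$$

i.e. the negative-weight term is down-weighted by $v^{-}/(v^{+}+v^{-})$.
The decisive practical property is that no thresholding is needed: the
algorithm consumes the full signed matrix, so the module decomposition is
free of the sparsification confound that affects every other metric.

Optimization is a generalized Louvain scheme on the signed modularity
matrix: greedy single-node moves to the best neighbouring community,
aggregation of communities into super-nodes, recursion, and a final
node-level refinement sweep; the node visit order is randomized per
restart (`signed_modularity_partition()`, `best_partition()`). The number
of modules is decided by the objective itself. On all signed graphs with 8
nodes we verified (by exhaustive enumeration of all 4140 set partitions)
that 50 restarts reach the global optimum in at least 95% of random
instances; this equivalence check is part of the acceptance tests.

When a fixed module count $K$ is required, we keep the best restart that
naturally produced $K$ modules; if none did, the best partition is
repaired — merging the community pair whose merge costs the least
modularity while $K$ is too large, spectrally bisecting the largest
community while $K$ is too small. The repair is a mechanism of this
package's choosing: fixing $K$ is stated in the protocol we follow, but no
mechanism is given there.

### Participation and its ranks

Given a partition, the participation index of node $i$ is
$\mathrm{PI}_i = 1 - \sum_m (s_{im}/s_i)^2$ over the nonnegative weights
of the *thresholded* graph: 0 when all strength stays in the node's own
module, approaching 1 for an even spread (a "connector"). Within each
subject, PI values are rank-transformed (ascending, average ranks on ties)
to remove inter-subject scale differences before any group comparison.

Two decomposition policies feed PI, matching the two workflows:

* **group analysis** uses one *consensus* partition for all subjects, so
  node-wise group differences reflect the relation of nodes to a common
  modular frame, not differences between frames;
* **classification** uses each subject's own best 5-module decomposition,
  so no group-level information leaks into single-subject features.

The consensus procedure is iterative co-assignment clustering: per-subject
best partitions vote into a node-by-node co-assignment matrix, each
subject weighted by its modularity $Q$ (clamped at 0, so an unstructured
subject contributes nothing); the matrix, centred on its mean off-diagonal
agreement, is re-partitioned until all restarts agree or the result is
stable across iterations, then constrained to $K$ modules. This is our
stand-in for a consensus weighting whose exact original form is not
public; it is intentionally confined to one function
(`group_consensus_partition()`). Per-subject partitions are computed with
a seed that does not depend on subject order, making the consensus exactly
equivariant under relabelling of subjects.

## Sparse graphs and topological metrics

All other metrics require sparse graphs. `threshold_graph()` removes
edges in ascending weight order until only a target fraction (default 12%,
i.e. 536 of 4465 edges at $N=95$) remains; negative weights are never
retained, and any edge whose removal would disconnect the graph is kept
even if weak, so the output is always a single component. When the bridge
rule makes the target unreachable the minimal connected graph is returned
and flagged. The implementation takes a shortcut worth documenting: if the
target-count strongest edges already span the graph, no weaker edge can
ever be a bridge during the greedy sweep, so that edge set *is* the exact
greedy result; otherwise the removal is simulated edge by edge. The
equivalence with the naive simulation is tested on small graphs.

On the thresholded graph we compute weighted path length, global and
local (Latora–Marchiori) efficiency, Onnela-form weighted clustering, and
shortest-path betweenness, all with edge lengths $1/w$ — the standard
convention of the field's toolboxes, since the protocol we follow does not
name one. Degree-preserving random references (double-edge swaps that
carry weights and reject disconnecting swaps; 20 references, 10 swap
attempts per edge by default) normalise clustering and path length, and
the small-world index is their ratio. The ensemble size is our choice;
the original statement prescribes normalisation but not a count.

The threshold sweep (10–35% in 1% steps, 26 points) and its trapezoidal
area-under-curve pooling reproduce the whole-brain comparison protocol;
Welch $t$ tests are applied per threshold and to the subject-wise AUCs.

## Group statistics

Node-wise group differences in PI ranks use Welch's $t$ (no test statistic
is prescribed by the protocol; unequal variances are the safe default).
Multiplicity is handled by a permutation scheme: subject labels are
permuted globally (preserving the dependence between nodes), the permuted
$t$ statistics are pooled across nodes and permutations into one null
distribution — the statistics are studentised, hence comparable across
nodes, and pooling gives p-value resolution far below $1/(B+1)$ — and
Benjamini–Hochberg step-up is applied to the permutation p-values at $q =
0.05$. The `n_perm = 1000` default keeps the smallest attainable p-value
well under the BH threshold at 95 nodes.

The global-signal control summarises each subject by the temporal standard
deviation of the across-region mean signal (the series are zero-mean, so
the temporal mean carries no information) and compares groups by Welch's
$t$.

## Classification

The feature matrix has one column per (metric, node) pair over eight
node-wise metrics — PI, degree, strength, betweenness, clustering, local
and global nodal efficiency, and their ratio — 760 columns at $N=95$.

Feature ranking is minimum-redundancy maximum-relevance in its
mutual-information-difference form: features are discretised into three
bins at mean ± SD, the first feature maximises MI with the class label,
and each next feature maximises relevance minus mean MI with the already
selected set. Two numerical choices matter. The SD is the population
(1/n) form with closed outer intervals, so a two-valued feature falls into
the outer bins instead of collapsing into the middle bin (with the sample
SD and open intervals, a feature identical to the labels would score zero
information — a degenerate corner we hit and fixed). Recursive feature
elimination (iterated linear-SVM weight pruning) is available as an
independent ranking for comparison.

The bagging protocol draws, per iteration, a random half split rejected
until both halves' class shares lie in [0.4, 0.6] (the exact discarded
ratios are not legible in the source protocol; the band is configurable),
ranks features by mRMR *on the training half only*, standardises by
training statistics, trains a linear SVM with $C = 1$, and records
selectivity (correct controls / all controls) and sensitivity (correct
patients / all patients) on both halves; 1000 iterations are averaged.
Nesting the feature selection inside each split is the only ordering under
which the two shuffle controls mean anything:

* **pre-shuffle** permutes all labels before selection and training — a
  full permutation null; test performance at chance certifies that no
  information leaks through selection or standardisation;
* **post-shuffle** trains on true labels but scores the test half against
  permuted labels — chance test performance with perfect training
  performance certifies the scoring path itself.

"Selectivity" is read as specificity; the source protocol never defines
it, and the specificity/sensitivity pair is the standard reading.

## The synthetic cohort generator

No patient data are distributed, so every downstream stage is exercised
on a generator whose defaults *are* the study conditions: 22 control and
21 patient subjects, 95 regions (45 mirrored homologue pairs plus 5
midline regions), 483 time points at TR 1.25 s, 5 planted bilateral
modules, and participation shifts in 20 down- and 9 up-affected nodes.

The population correlation of each group is assembled from:

* a logarithmic distance background $a + b\log d$ with $a = 0.55$,
  $b = -0.08$ per log-mm, clipped to $[-0.9, 0.9]$;
* a block contrast: +0.20 within planted modules, −0.15 across;
* a sparse *connector link* skeleton: node $i$ carries a connector
  propensity $c_i \sim \mathrm{Beta}(1.5, 3)$, and a cross-module pair
  $(i,j)$ receives a specific link with probability $0.35\,c_i c_j$ and
  strength uniform on
  $[0.35, 0.55]$. These links are what give nodes a nonzero participation
  after thresholding: with block contrast alone, the 12% strongest edges
  are almost all within-module and PI degenerates to 0 for every node. A
  uniform connector *offset* (rather than sparse links) fails in the
  opposite direction — it flips entire nodes across the boundary. Sparse
  strong links are also the more faithful picture of hub organisation;
* a symmetric structural jitter (SD 0.05) shared by both groups.

The patient effect reallocates a fraction `effect_size` (default 0.35) of
each affected node's positive covariance mass across the module boundary:
down-affected nodes (drawn among nodes with realised link mass ≥ 0.3 — a
node must have cross-module coupling to lose) move cross-module mass
inside; up-affected nodes (drawn among embedded nodes) move within-module
mass outside, concentrated on their 2 strongest receiving partners —
recruited coupling attaches to specific regions, and a diffuse gain would
vanish at thresholding. Mass moves only along edges to unaffected
partners, so planted shifts cannot cancel each other. The result is
repaired to the nearest positive semidefinite matrix by eigenvalue
clipping at $10^{-6}$ and rescaled to unit diagonal. The effect size is a
calibration choice (the source reports rank maps, not effect sizes),
fixed so the default cohort is separable by the classifier.

Subjects are independent zero-mean multivariate normal draws from their
group matrix. Temporal autocorrelation, hemodynamics, head motion,
scanner noise and voxel-level structure are deliberately *not* modelled:
the pipeline consumes only zero-lag correlations, so passing tests
demonstrate the statistical machinery on correlation structure — they do
not validate preprocessing choices on real BOLD data, and real cohorts
will have heavier inter-subject variability than the finite-$T$ sampling
noise modelled here.

## Numerical choices and degenerate inputs

* Half-away-from-zero rounding for the retained-edge target; a one-edge
  discrepancy is tolerated and flagged.
* Zero-variance regions abort correlation with the region named; an
  all-zero matrix aborts community detection; a disconnected positive
  part aborts thresholding.
* Welch tests with zero pooled standard error return $t=0$, $p=1$ when
  the means agree (identical data), $p=0$ otherwise.
* All randomness flows from one root seed through a fixed integer
  derivation, so cohorts, partitions and bagging runs are bit-reproducible
  and independent components do not share streams.
* Louvain ties are broken by the first maximal gain; restarts vary the
  node order, which is where the stochasticity lives.

## Problem sizes used in the checks

The verification suite runs the exhaustive-modularity comparison on 50
signed 8-node graphs; the metric cross-checks on 50 weighted graphs of
6–10 nodes; the thresholding contract on 100 generator-drawn 95-node
matrices; module recovery, detection power (`n_perm` = 1000) and the three
1000-iteration classification conditions on the full 43-subject default
cohort; and false-discovery control on 200 null cohorts of 10+10 subjects,
30 regions, 120 time points and 3 planted modules with `n_perm` = 500 —
a size at which 200 complete pipeline passes remain comfortable on a
single CPU while exercising every stage end to end.

## Known limitations

* The distance penalty is a log-linear OLS residual; if the original
  penalty equation differs in form, coefficients are not comparable,
  though the module interface isolates the swap.
* The consensus algorithm is a reconstruction (Q-weighted co-assignment
  with iterative re-clustering), not the original pseudo-code.
* PI is computed on thresholded nonnegative strength shares in both
  workflows; an unthresholded signed variant would be more sensitive (the
  generator experiments showed roughly twice the detection power without
  thresholding) but would depart from the stated protocol.
* The mRMR discretisation is coarse by design; features with information
  concentrated inside ±1 SD of their mean are under-valued.
* With ~21 subjects per group, the SVM's training fit is always perfect
  on separable cohorts; training rates carry no generalisation
  information — the test-half rates and the two shuffle controls do.
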