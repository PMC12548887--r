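---
title: "Multilayer network path analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilayer network path analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlnpaths)
```

# The problem

Multimodal cohort studies of neurodegeneration measure the same subjects at
several biological scales — genetic markers, CSF/plasma molecular
concentrations, PET and MRI imaging features, clinical risk factors, and
cognitive/diagnostic phenotypes — but rarely all of them on all subjects.
`mlnpaths` treats each modality as one *layer* of a multilayer network and
asks two questions:

* **Structure**: which variable pairs, within and between layers, share
  information, and is the layer organization reflected in the network's
  connectance?
* **Flow**: when a single variable is perturbed periodically, along which
  chains of variables does that perturbation propagate most strongly down to
  the phenotype layer?

# Association model

Every pair statistic is computed on the *pairwise-complete* subjects (both
values observed). Dependence is measured two ways:

* **Binned mutual information** (nats). Continuous variables are partitioned
  into equal-width bins over the observed pairwise-complete range;
  binary/categorical/ordinal variables use their observed levels. With
  joint bin counts $n(i,j)$ and marginals $n_x(i), n_y(j)$ out of $N$
  complete pairs, the plug-in estimate is
  $\hat I = \sum_{ij} \frac{n(i,j)}{N}\,
  \log\frac{n(i,j)\,N}{n_x(i)\,n_y(j)}$, with empty cells contributing
  nothing. Edge weights use the normalized form
  $\hat I / \sqrt{\hat H_x \hat H_y}$ (geometric-mean normalization,
  clipped to $[0,1]$; defined as 0 when either entropy vanishes).
* **Pearson correlation**, whose sign later distinguishes activating from
  inhibitory influence in the dynamic model.

Significance is assessed by permutation: the second variable is relabeled
`n_perm` times over the complete pairs, and
$p = (1 + \#\{\text{permuted} \ge \text{observed}\}) / (1 + n_{perm})$
(add-one estimator, so $p > 0$ always; finite-sample valid). MI tests are
one-tailed (only an excess of dependence is interesting); Pearson tests are
two-tailed (the sign matters). Pairs with $p < \alpha$ become edges.

**Parameters.**

| parameter | default | rationale |
|---|---|---|
| `n_bins` (continuous) | $\lceil\sqrt{n/5}\rceil$, in $[2,10]$ | keeps expected cell counts usable at cohort $n$; the binning *method* is fixed but the count is an estimation choice |
| `n_perm` | 1000 | resolves $p$ down to $10^{-3}$; the add-one estimator keeps the test valid at any count |
| `alpha` | 0.05 | conventional edge-inclusion level; no multiplicity correction, matching the raw-threshold design |

The geometric-mean NMI normalization, the one-/two-tailed split, and the
equal-width (not equal-frequency) bins are package decisions: the naming
"normalized mutual information" admits several normalizations and the
equal-width partition follows the plain reading of fixed-size support bins.
Per-pair permutation streams are seeded from a master seed plus the pair
name, so single pairs are reproducible in isolation and pairs are mutually
independent.

# Networks and connectance

Within-layer networks, inter-layer edge sets, and their union (the
multilayer network) all use the MI criterion and NMI weights; the network
used for dynamics is built separately over all variables jointly with
signed Pearson weights and its own two-tailed permutation threshold (rather
than inheriting the MI topology — the two networks answer different
questions, and which construction applies is a config switch with the
separate construction as default). Disconnected nodes are retained.

Layer organization is summarized by the connectance matrix: within-layer
weighted density $d = 2\sum w / (|V|(|V|-1))$ on the diagonal, bipartite
weighted density $d_{bip} = \sum w / (|V_i||V_j|)$ off it. The average
shortest path length uses edge length $1/w$, so strong connections are
short.

# Boolean dynamics under forcing

Node states are binary. Synchronously, every node's next state is *active*
iff $\sum_u w(u,v)\,s(u) > 0$ where $s(u) \in \{0,1\}$: inactive neighbors
contribute nothing, exact ties and isolated nodes go inactive. One input
node is clamped to a square wave (`half_period` = 10 steps per phase) for
`steps` = 100 iterations; every other node flips its state with probability
`noise_prob` = 0.05 per step. Initial states are active with probability
0.5. Within a step the order is clamp → synchronous update → noise: the
clamped value is visible to neighbors in the same step, the input itself is
exempt from both update and noise (it is under full experimental control).
The operation order and the flip (rather than resample) noise model are
package decisions recorded in the simulation config.

A consequence of this update rule worth knowing: on *undirected, mutually
positive* subgraphs, deactivation cannot propagate — once a node and one of
its positive neighbors are both active they sustain each other, so without
noise such subgraphs saturate active after the first forcing phase. The
noise term is therefore not cosmetic: it is what lets the forcing signal
re-imprint on strongly interconnected positive cliques. On feedback-free
topologies (e.g. a hub-forced star) the noise-free traces follow the wave
exactly, and the test suite checks both regimes.

# Cross-correlation path scores

For each *existing* edge of the signed network (no new edges are ever
introduced), the maximal Pearson cross-correlation between the two nodes'
activity traces is taken over integer lags in $[-\text{max\_lag},
\text{max\_lag}]$ with `max_lag` defaulting to the forcing half-period
(larger shifts are not phase-meaningful). Zero-variance segments define
correlation 0; ties prefer the smallest absolute lag. Edge length becomes
$1/cc$; edges with $cc \le$ `cc_floor` ($10^{-3}$) — including all
non-positive maxima, whose reciprocal would be meaningless — are dropped.

The score of a path is the sum of its edge lengths, so it prefers few hops
*and* high cross-correlations; since $cc \le 1$, the score is bounded below
by the hop count. The $k = 10$ lowest-score loopless paths per
(input, target) pair are computed with a Yen-type k-shortest-paths search,
expanded until the score tie-class at rank $k$ is fully captured and then
ordered deterministically by (score, lexicographic node sequence). One
simulation is run per input node (sub-seed derived from the master seed);
averaging over repeated simulations is available in the config but off by
default, matching the single-run design.

# Negative controls

Specificity is tested against degree-preserving network permutations:
repeated double-edge swaps $((a,b),(c,d)) \to ((a,c),(b,d))$ with uniform
choice of rewiring and rejection of self-edges and duplicates, counting
*attempted* swaps — 10 per edge — with the acceptance rate logged; then the
signed weights are shuffled over the new edge set (the weight multiset is
conserved, signs travelling with weights). Each permuted network reruns the
full simulation + path extraction, and every original path is classified:
reappears as a top path / exists topologically but not top / absent. A path
*passes* when its top-path fraction is below 1% (with 100 networks: never a
top path). The stricter existence-based rule is available as a config
switch, and both fractions are always reported, because a path that merely
exists topologically in a permuted network says little against its dynamic
specificity.

This control is *permissive by construction*: rewiring destroys most
specific node sequences, so paths are usually absent from permuted networks
and therefore pass. It guards against hub-driven artifacts (paths that are
top merely because of the degree sequence), not against noise in the
cross-correlation ranking.

# The synthetic cohort generator

There is no redistributable reference dataset, so validation uses a
latent-Gaussian factor model with known ground truth:

* **Blocks**: variables in a within-layer block load on a shared factor
  with loading $\lambda$; the population correlation between two members is
  $\lambda^2$ (at `noise_sd` = 1).
* **Chains**: planted cross-layer chains propagate autoregressively —
  each chain variable's latent is `strength` times the previous one plus
  independent noise — so consecutive pairs correlate at `strength` and
  correlation decays as `strength`$^d$ with chain distance. (A single
  shared chain factor would make *all* chain pairs equally dependent and
  erase the sequential structure the recovery oracles test.) Chains can be
  restricted to one diagnostic group.
* **Kinds**: binary variables threshold the latent at 0; categorical and
  ordinal variables quantile-bin it into equiprobable levels, preserving
  monotone dependence so binned MI still detects it.
* **Missingness**: whole layers are masked per subject,
  missing-completely-at-random, emulating per-modality availability;
  pairwise-complete estimation is unbiased under MCAR.

The default study conditions (`default_cohort_spec()`): 1000 subjects,
group fractions 622:807:533 (control:MCI:AD, a typical cohort mix), six
layers of ~60 mixed-type variables, correlated blocks in the PET (loading
0.85), MRI (0.9) and molecular (0.75) layers, per-layer missingness between
0.05 (genetic, phenotype) and 0.25 (molecular), and one planted
genetic→PET→risk→phenotype chain at loading 0.7. These values were fixed
once as a realistic desk-scale emulation; the generator reproduces the
statistical skeleton (mixed types, blocks, chains, MCAR missingness) but
*not* real marginal distributions, site effects, longitudinal visits, or
informative missingness — so green tests certify the pipeline's mechanics
and recovery behavior, not clinical validity on real data.

# Numerical choices and degenerate inputs

* MI is reported in nats; tiny negative rounding of the plug-in sum is
  clamped to 0; NMI is clipped to $[0,1]$.
* Constant vectors: MI and NMI are 0 (not an error); Pearson is undefined
  and errors; pairs with a constant member simply carry no signed edge.
* Fewer than two complete pairs is an error for every statistic.
* Path ordering rounds scores to 9 decimals before the lexicographic
  tie-break so float noise in equal-score sums cannot reorder ties.
* Degenerate permutation inputs (fewer than two edges) return a
  weight-permuted copy with a warning; a triangle admits no valid swap and
  only its weights shuffle.

# Validation scale and known limitations

The test suite validates each stage against independent oracles (direct
plug-in summation for MI, exhaustive simple-path enumeration for the path
search, binomial/closed-form checks elsewhere) and runs the full recovery
experiment at desk scale: 1000 subjects, ~60 variables, 20 seeds, 20
permuted networks standing in for 100, 200-permutation calibration batches
where the full 1000 would only slow the suite without changing resolution
at the 0.05 level.

Limitations to keep in mind:

* With a single 100-step simulation per input, cross-correlation estimates
  on noisy traces have high variance; path ranks among competing paths
  through the same strongly dependent variables are correspondingly
  unstable. The planted-chain recovery experiment sits near its acceptance
  boundary for exactly this reason, and the saturation behavior described
  above keeps chain cross-correlations noise-driven when all planted
  dependencies are positive.
* The permutation control certifies degree-sequence specificity only; under
  a structureless generator almost every extracted path passes it, because
  absent paths pass by definition.
* MI estimation uses the plain plug-in estimator (positively biased by
  roughly $(b_x-1)(b_y-1)/2N$); the permutation test calibrates the
  *decision*, not the point estimate.
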