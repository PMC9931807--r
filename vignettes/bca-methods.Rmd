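---
title: "Microcircuit structure learning by node-wise Markov blanket discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microcircuit structure learning by node-wise Markov blanket discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bcanet)
```

## The problem

A functional microcircuit is the mesoscopic network of statistical
associations among the activity traces of a neural population: nodes are
neurons, edges are *direct* associations. The standard construction —
thresholded pairwise correlation — cannot distinguish a direct association
from one mediated by a third neuron or by common drive, and therefore tends
to return dense graphs. `bcanet` instead treats the microcircuit as the
graph of a pairwise Markov network and poses structure learning as a
*Markov blanket discovery* problem: the neighbors of node $X_i$ are exactly
the minimal set of nodes that renders $X_i$ conditionally independent of all
the others, i.e. the set most predictive of $X_i$ once jointly conditioned
on.

## Model

For binary spike matrices we use the Ising model with fields,
$$U(\mathbf x) = -\Big(\sum_i r_i x_i + \sum_{i<j} w_{ij} x_i x_j\Big),
\qquad P(\mathbf x) \propto e^{-\beta U(\mathbf x)},$$
where $w_{ij}\neq 0$ exactly when $i$ and $j$ are adjacent. For continuous
traces (e.g. normalized fluorescence) we use the Gaussian Markov network:
adjacency is carried by the nonzero off-diagonal entries of the precision
matrix $\Sigma^{-1}$. Both models place the structural information in the
same object — the neighborhood of each node — which is what the learner
estimates.

Two conventions worth making explicit:

* the pairwise sum counts each unordered pair once (equivalently
  $-(\mathbf r^\top \mathbf x + \tfrac12 \mathbf x^\top \Omega \mathbf x)$
  with symmetric $\Omega$);
* $\beta$ multiplies the energy in the exponent (an inverse-temperature
  convention). If you prefer $e^{-U/\beta}$, pass $1/\beta$.

## The learner

Estimating a node's neighborhood directly in the undirected model is
expensive. The package exploits the identity between a node's Markov blanket
in a Markov network and in a Bayesian network representing the same
distribution: in a DAG the blanket is parents $\cup$ children $\cup$
co-parents, and moralization (`moralize()`) turns it into the undirected
neighborhood. The learner therefore uses a deliberately restricted
Bayesian-network architecture in which the target node is a *leaf* and all
other nodes are candidate parents; maximizing a decomposable family score
over the parent set approximates the blanket. This is an approximate method
whose characteristic error is *omission*: the detected set tends to be a
subset of the true blanket, which is why the final combination step is an OR
across node-wise results.

Scores:

* **BDeu** (binary): the Dirichlet-multinomial log marginal likelihood of
  the target given the parent configuration counts, with a total equivalent
  sample size `ess` (default 1.0) spread uniformly over the $2^k$ parent
  configurations and 2 target states. Configurations never observed
  contribute nothing; unobserved levels are handled by the Dirichlet
  smoothing.
* **BIC** (continuous): the maximized Gaussian log-likelihood of the target
  regressed linearly on the parents, minus $(k/2)\log n$ with
  $k = \#\text{parents} + 2$. The ML residual variance is floored at
  `variance_floor` (default 1e-12) so a perfect predictor yields a finite,
  winning score; collinear parent columns are dropped (QR rank) and do not
  count toward $k$.

Search: greedy hill-climbing from the empty set, one addition or removal per
step, accepting the best move only if it improves the score by more than
1e-9 (a floating-point guard). Ties go to the lowest column index, so runs
are deterministic given the data. Swap moves are not used; additions and
removals preserve the leaf architecture and are the standard greedy
repertoire. `max_parents` is unlimited by default; a cap is available for
very wide data.

The full pipeline (`learn_microcircuit()`) is: drop zero-variance columns
(silent neurons), learn one blanket per remaining node, then connect $i$ and
$j$ if either detected the other (OR). Dropped nodes re-enter the output as
isolated nodes so evaluation against a full ground truth stays well-defined.
Per-node searches are independent, so results do not depend on scheduling.

## Baselines

Two comparison methods, intentionally standard:

* **Correlation**: all pairwise Spearman coefficients, two-sided p-values
  (large-sample t approximation; Monte-Carlo permutation null with 2000
  draws when $n < 30$, where exhaustive permutation enumeration would be
  infeasible), Benjamini–Hochberg correction applied jointly across all
  pairs, edge iff adjusted $p < \alpha$.
* **Regression**: node-wise L1-penalized logistic regression (via `glmnet`,
  100 lambdas down to $10^{-3}$ of the null-model lambda), model selection
  by extended BIC with $\gamma = 0.25$, neighborhoods combined across
  nodes. The neighborhood combination rule is not canonical; on the
  benchmark 6-node Ising model the OR rule reproduces this baseline's
  published behavior (all six true edges plus roughly two spurious ones)
  while AND is markedly more conservative, so OR is the package default and
  AND remains available in `regression_config()`.

`ensemble_combine()` provides the AND/OR ensembles of any two learned
graphs; AND $\subseteq$ each input $\subseteq$ OR always holds.

## Simulators

The package generates all of its own benchmark data.

**6-node Ising benchmark** (`six_node_model()`): zero fields, $\beta = 2$,
couplings $w_{12}=w_{14}=w_{23}=w_{34}=0.5$, $w_{45}=-0.8$, $w_{56}=0.9$;
6 true edges, 9 empty pairs. Sampling is single-site Metropolis–Hastings
with acceptance $\min(1, e^{-\beta\,\Delta U})$, burn-in 5000 sweeps,
thinning 10 sweeps per kept configuration (one sweep = $M$ proposed flips).
The exact 64-state enumeration (`ising_exact_distribution()`) serves as the
sampler's oracle in the tests. The field coefficients are not part of the
benchmark's published description; zero fields are assumed.

**Integrate-and-fire network** (`simulate_lif()`): 50 stimulus-driven
group-A neurons and 50 group-B neurons, each B wired to 2 random A parents.
Per 5 ms frame, $V \mathrel{+}= dt\,(V_{rest}-V)/\tau + \sigma\varepsilon
\tau^{-1/2}$ plus inputs; a spike fires when $V > 1$ and resets $V$ to
$V_{rest} = 0$. $\tau_A \sim N(20, 5^2)$ ms (clipped at 1 ms),
$\tau_B = 100$ ms, $\sigma = 0.2$, synaptic increment $a = 0.8$ applied on
the frame after a parent spike, 1200 frames, stimulus every 3 or 4 frames.
The ground truth connects B pairs sharing at least one parent
(`shared_parent_graph()`); with 49 B neurons the expected edge count is
$\binom{49}{2}\big[1 - \tfrac{48\cdot47}{50\cdot49}\big] \approx 93$.

The stimulus mechanism deserves a note, because it is the one genuinely open
design choice. The stimulus drive is a global increment `stim_gain` to every
A neuron's potential on stimulus frames. A supra-threshold value (e.g. 1.2
with threshold 1) makes every A neuron fire deterministically on every
stimulus frame; every B neuron then receives $2a = 1.6$ on the following
frame and all group-B traces become identical — a degenerate regime in which
shared-parent structure is unidentifiable and no B neuron can be silent. We
therefore set `stim_gain = 1.0`, exactly at threshold: each A neuron's
response on a stimulus frame is decided by its accumulated membrane noise,
approximately an independent fair coin per neuron. This retains the strong
common drive that makes *marginal* correlations dense across all of group B
(the regime in which the correlation baseline saturates) while the
*conditional* structure still reflects which parents a B neuron actually
has. The value is exposed in `lif_config()`.

Analysis of this simulation is restricted to group B — the study design
examines coherence among the downstream population, and conditioning on the
upstream drivers would (correctly) explain away the B–B dependencies the
ground truth encodes.

**Gaussian chains and the two-subtype trial collection**:
`chain_gmn_params()` builds tridiagonal-precision chains (default partial
correlation 0.45) for continuous-mode benchmarks.
`generate_trial_collection()` emulates a per-trial imaging study with two
trial types: type "a" trials sample from a 20-node chain, type "b" from a
chain over the odd-then-even node ordering (edge-disjoint from "a", equal
density, partial correlation 0.35), 300 samples per trial by default — the
order of frames available in a single behavioral trial. `flip_noise` toggles
a fraction of each trial's precision edges to model per-trial structural
variability; positive definiteness is restored, when needed, by shrinking
off-diagonals.

What the surrogate does *not* emulate: calcium indicator dynamics
(rise/decay kernels), temporal autocorrelation within a trial, shared
baseline drift, or the marginal statistics of fluorescence traces. Passing
the subtype benchmark therefore shows that the similarity-clustering
pipeline resolves structural subtypes at realistic trial counts and lengths,
not that it is robust to every artifact of real imaging data.

## Subtype pipeline

Per-trial graphs are compared by the Sørensen–Dice coefficient of their edge
sets, $2|E_a\cap E_b|/(|E_a|+|E_b|)$ (defined as 1 when both are empty:
identical objects). The similarity matrix, with self-loops removed and
weights below 1e-12 dropped, feeds multi-level (Louvain) modularity
optimization at resolution 1.0; the vertex-visit order is randomized, so a
seed argument makes clustering reproducible. Each cluster's representative
is its member with maximal mean similarity to co-members (ties to the lowest
index). Graph-level centrality is the node average of betweenness
(unnormalized node scores by default; a normalization toggle exists) or of
the principal adjacency eigenvector taken nonnegative and scaled to unit
Euclidean norm — undefined, and reported as an error, on edgeless graphs.
Subtype contrasts use a pooled-variance two-sample t-test (Welch available);
the pooled variance is floored so perfectly separated constant groups give a
huge $|t|$ rather than 0/0. Cluster-to-type accuracy is cluster purity:
each cluster votes its majority type.

## Problem sizes and numerical choices

The package's own benchmarks run at the published scales: 5000 Ising
configurations, 1200 simulation frames, 10 (6-node) or 5 (integrate-and-
fire) seeds, 25 + 25 trials of 300 samples. The exact-enumeration oracle is
limited to 20 nodes by design; the sampler-vs-oracle comparison uses
Monte-Carlo standard errors at 3 SEs. Precision entries are declared nonzero
at 1e-8 relative to the largest off-diagonal entry. All randomness flows
through explicit seed arguments (R's RNG also drives the C++ samplers), so
every experiment is replayable bit-for-bit.

## Known limitations

* Blanket discovery by leaf-node search is approximate: its guarantee runs
  in one direction (subset of the truth), so sensitivity leans on the OR
  combination and can still fall short for weakly coupled nodes at small
  $n$.
* The learned adjacency is unweighted and unsigned; edge directions in the
  internal computations carry no causal meaning.
* Mixed binary/continuous data are out of scope, as are blanket methods
  based on conditional-independence tests.
* The correlation baseline's permutation p-values for $n < 30$ are
  Monte-Carlo, not exhaustive.
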