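---
title: "Prioritizing network communities by structural robustness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing network communities by structural robustness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crankr)
library(dplyr)
```

## The problem

Community detection methods partition (or cover) a network with tens to
hundreds of communities but say nothing about which ones deserve follow-up.
In biological applications — protein interaction modules, drug communities,
cell–cell similarity clusters — downstream validation is expensive, so the
communities most likely to correspond to real structure should be examined
first. crankr ranks detected communities using network structure alone: no
annotation, labels or metadata are required.

## The prioritization model

The premise is that a high-priority community scores highly on structural
quality metrics *and* that those scores are stable when the network is
slightly perturbed. Perturbation is modeled as degree-preserving rewiring of
a fraction $\alpha$ of the edges: at $\alpha = 0$ the network is untouched,
at $\alpha = 1$ it is a random graph with the original degree sequence (the
configuration model). For every structural feature $f$ taking values in
$[0,1]$, the prioritization score of community $C$ is

$$ r_f(C;\alpha) \;=\; \frac{f(C)}{1 + \lvert f(C) - f(C\mid\alpha)\rvert }, $$

where $f(C\mid\alpha)$ is the feature under the perturbed network. The score
equals $f(C)$ for a maximally robust community, decreases as the feature
drifts under rewiring, and is zero when the feature itself is zero. The
default perturbed evaluation level is $\alpha = 0.15$: strong enough to
disrupt coincidental structure, weak enough to preserve genuine modules.

### Analytic perturbation instead of physical rewiring

Physically rewiring a network (and re-evaluating every metric on many
rewired copies) is expensive. crankr instead evaluates edge probabilities
under perturbation in closed form as a mixture with the configuration-model
expectation:

$$ p(u,v \mid \alpha) = (1-\alpha)\, p(u,v) + \alpha \min\!\Big(1,
   \frac{k_u k_v}{2m}\Big). $$

This form is exact at both ends: at $\alpha = 0$ it returns the observed
probability and at $\alpha = 1$ the configuration-model edge probability.
Between the ends it is *linear* in $\alpha$, which no physical
degree-preserving rewiring process reproduces exactly: when a fraction
$\alpha$ of edges is physically selected and re-matched, a selected edge is
destroyed with certainty and re-created only with probability of order
$\alpha\, k_u k_v / 2m$, so empirical edge survival is
$(1-\alpha) + O(\alpha^2 \bar q)$ rather than $(1-\alpha) + \alpha \bar q$.
On the 300-node benchmark at $\alpha = 0.15$ the analytic mean exceeds the
Monte-Carlo survival frequency by about $\alpha(1-\alpha)\bar q \approx
0.011$ — far beyond Monte-Carlo noise, and an intrinsic property of the
closed form, not an implementation artifact. The package ships the physical
rewirer (`rewire_network()`) purely as a test oracle; the test suite asserts
the exact agreement at both limits and the first-order bound
$\alpha(1-\alpha)\bar q$ at intermediate intensity. Because the aggregation
step consumes only *rankings* of communities, a uniform first-order offset
in edge survival has no effect on the final prioritization.

The perturbed community contribution $p_C(u,v\mid\alpha)$ uses the same
mixture with the configuration-model term scaled by the community's share
of the total edge probability, $\min(1, p_C(u,v)/p(u,v))$, so that a
community which explains little of an edge also gains little from the
rewiring null.

## The four metrics

A community model supplies three quantities for any node pair and
community: the membership probability $p_C(u)$, the edge probability
$p(u,v)$, and the community's contribution to the edge, $p_C(u,v)$. On top
of these crankr computes, at $\alpha = 0$ and $\alpha = 0.15$:

* **Likelihood** — how well the community explains the presence *and*
  absence of edges among its members: the product over members of
  $p_C(u)$ and over ordered member pairs of $p_C(v)\,p_C(u,v\mid\alpha)$
  for observed edges and $p_C(v)\,(1 - p_C(u,v\mid\alpha))$ for non-edges.
* **Density** — the joint probability of the observed internal edges under
  the *unconditioned* $p(u,v\mid\alpha)$, which lets enclosing or
  overlapping communities contribute.
* **Boundary** — the accumulated evidence against edges leaving the
  community: the product of $1 - p(u,v\mid\alpha)$ over all pairs with one
  endpoint inside and one outside.
* **Allegiance** — the fraction of members whose summed perturbed edge
  probability toward neighbors inside the community is at least as large as
  toward neighbors outside.

### Numerical conventions

Three choices matter in practice and are deliberate:

* **Geometric-mean normalization.** Likelihood, density and boundary are
  raw products whose magnitude collapses exponentially with community size;
  comparing raw products across communities of different sizes would let
  tiny communities dominate every ranking. Each product is therefore
  reported as $\exp(\text{mean log-factor})$. Within a fixed community this
  is a monotone transform (so each community's robustness score is
  unaffected in spirit), and across communities it makes values of
  different sizes commensurable in $[0,1]$.
* **Probability clipping.** Every queried probability is clipped to
  $[10^{-9}, 1-10^{-9}]$ before logs. Crisp (hard-assignment) adapters emit
  exact 0s and 1s which would otherwise annihilate whole products: a single
  observed boundary edge would drive the boundary metric of an otherwise
  well-separated community to exactly zero.
* **Pair orientation.** The likelihood's pair factor contains $p_C(v)$ and
  is therefore asymmetric in $(u,v)$. The pair product runs over *ordered*
  pairs (both orientations), which makes the metric symmetric and hence
  invariant under node relabeling; with the geometric mean this merely
  reweights membership against edge factors.

Communities with no internal edge get density 0 (not the empty product 1):
an internally disconnected node set must not outrank genuine modules. A
community covering the whole network has an empty boundary and boundary
metric 1. Boundary evaluation enumerates all cross pairs exactly for
networks up to 2000 nodes; beyond that it switches to negative sampling
(observed boundary edges exactly, plus 50 uniformly drawn non-neighbor
outside nodes per member, scaled up; sampling is without replacement, so a
full budget reduces exactly to enumeration, and the estimator is unbiased
in log space).

## Combining the metrics

Each metric yields a ranked list of communities (descending value, ties by
community ID). The lists disagree, and their reliability varies by network
and detector, so they are combined by an unsupervised iterative scheme:

1. Partition each list's ranks into equally sized contiguous **bags**
   (default $\max(5, \lceil n/10\rceil)$ bags, capped at 50).
2. Initialize the aggregate as the mean rank across lists.
3. Treat the current top communities (one bag's worth by default) as a
   **temporary gold standard**; re-weight every (list, bag) with a
   Bayes-factor-style ratio $K = (g + 1)/(e + 1)$ of observed to expected
   gold-standard counts in the bag, capped to $[1/20, 20]$.
4. Re-score every community as the importance-weighted **mean** of its
   ranks, with weights $w = \log(K + 1)$, average that with the previous
   score (a damped update), and re-rank ascending.
5. Repeat from step 3 until the order stops changing (at most 100
   iterations; convergence is reported).

Two design points deserve a note. A weighted *sum* of ranks — even with
nonnegative weights — is not monotone in rank across bag boundaries, so it
cannot reproduce a single input list unchanged, and four identical lists
would not be a fixed point; the weighted *mean* preserves both properties
while still letting informative lists (large $K$) dominate disagreements.
And weights are recomputed fresh each iteration rather than accumulated
multiplicatively, which keeps the iteration a fixed-point map on orderings
and makes convergence checkable as exact order equality. Without damping
the pure map occasionally oscillates between two orders — a community near
a bag boundary of its own aggregate alternately gains and loses weight —
so the rescoring keeps a running average of the weighted mean ranks (a
damped update with step $1/t$); every genuine fixed point satisfies
score = proposed and is unaffected, and the first step is exact. A residual
period-2 oscillation means the damped scores are converging to an exact tie
between the alternating communities; it is detected and resolved by ranking
at the limit (the mean of the two alternating score proposals), with the
standing community-ID tie-break — reported via the `cycle_resolved` flag.
The procedure contains no randomness; identical inputs give identical
prioritizations.

## Community models

The metrics run downstream of any detection method through a small
contract: `membership_prob`, `edge_prob`, `comm_edge_prob`. Two providers
ship with the package.

**Crisp adapter** (`crisp_model()`): hard assignments become 0/1
memberships; edge probabilities are the observed edge weights. This adapts
any detection method's output.

**Affiliation model** (`fit_affiliation_model()`): nonnegative affiliation
strengths $F_{uC}$ under the noisy-OR edge model
$p(u,v) = 1 - \exp(-\epsilon - F_u\!\cdot\!F_v)$, fitted by block
coordinate ascent with a backtracking line search (each row update cannot
decrease the log-likelihood; the trace is monotone). The background
intensity defaults to the network density $2m/n(n-1)$. Initialization
seeds each community on a locally-minimal-conductance closed neighborhood
(greedily chosen to be disjoint), with small uniform noise elsewhere: pure
uniform random initialization provably traps coordinate ascent — a row at
zero has a nonpositive gradient whenever its community is dominated by a
distant region, so entire modules can remain permanently unassigned (two
disjoint cliques end up both explained by one community). The
neighborhood seeding is deterministic given the seed, which only fills
leftover slots. Communities are read off either by thresholding
$F_{uC} \ge \ln 2$ (membership probability at least 0.5; overlapping,
possibly partial cover) or as an argmax partition.

## The planted-partition benchmark

`generate_sbm()` creates stochastic block model networks with 10 planted
communities of 30 nodes: five blocks at within-block edge probability
$p_{\text{in}} = 0.6$ and five at $p_{\text{in}} = 0.2$, with cross-block
probability $p_{\text{out}} = 0.05$ by default. The low-density blocks sit
close to the detectability limit, so a detector recovers them only
partially — exactly the regime where prioritization is informative. The
cross-block probability is a configuration parameter (0.02–0.1 are all
reasonable); 0.05 yields connected networks in which the sparse blocks are
hard but not hopeless.

Each replicate: generate a network, fit the affiliation model with
$k = 10$ in argmax-partition mode, rank the detected communities by the
aggregated robustness metrics and by three baselines (per-community
modularity $e_C/m - (\mathrm{vol}_C/2m)^2$, descending; conductance
$\mathrm{cut}(C)/\min(\mathrm{vol}(C), \mathrm{vol}(V\setminus C))$,
ascending; a seeded random permutation), and score every ranking by
Spearman's $\rho$ against the gold standard. The gold standard matches
each detected community to the planted block with the largest overlap and
scores it by the fraction of its nodes inside that block; gold ranks use
average ranks for tied accuracies. The argmax partition matters here: pure
thresholding yields small node subsets that are each perfect subsets of one
block, collapsing the gold standard into ties that no ranking can resolve.

The benchmark runs 100 replicates by default (confidence intervals via the
normal approximation). A 100-replicate run takes a few minutes on one CPU;
all sub-seeds derive deterministically from one base seed. In the test
suite, checks that a mean correlation equals zero use 3-standard-error
(99.7%) intervals rather than 95% ones: with fixed seeds a 95% check fails
by construction in one run out of twenty, which is the wrong trade-off for
a deterministic suite.

## What the synthetic benchmark does and does not show

The generator emulates networks with known modular structure of
heterogeneous detectability — the one setting where an objective gold
standard for *prioritization* exists. It does not emulate degree
heterogeneity within blocks, overlapping planted communities, weighted or
directed edges, or the size and sparsity of real biological networks.
Passing the benchmark therefore shows that the pipeline orders communities
by recoverable structure under a known null; it does not certify
performance on any particular real network, where detector quality and
community-size distributions differ.

## Known limitations

* The analytic perturbation is a first-order surrogate for physical
  rewiring (see above); quantities derived from it should be read as
  ranking signals, not as calibrated survival probabilities.
* The affiliation fitter optimizes a non-convex objective; different seeds
  can give different local optima. Fits are bit-reproducible per seed.
* Overlapping communities are supported throughout the metrics, but the
  benchmark's planted truth is a partition.
* The detector behind published benchmark figures of this kind is
  generally not recoverable; with a different contract-satisfying detector
  the baseline correlations (modularity in particular) can shift
  substantially, because they depend on the size and purity profile of the
  *detected* communities rather than on the prioritization method itself.
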