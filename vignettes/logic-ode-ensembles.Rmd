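---
title: "Logic-based ODE ensembles for signaling network inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Logic-based ODE ensembles for signaling network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elodin)
```

## The problem

Perturbation screens of signaling pathways measure a handful of protein
activities over time while ligands are switched on or off and kinases are
chemically inhibited. The inference task is doubly hard: recover the directed
interaction network among the measured species, *and* produce a dynamic model
that predicts trajectories under perturbations never used in training. The
problem is ill-posed — few species are observed, sampling is sparse, and many
parameter/structure combinations explain the same data — so `elodin` follows
an ensemble strategy: many plausible network scaffolds are sampled from the
data, each is turned into a trainable dynamic model, each model is pruned to
the complexity the data support, and predictions are pooled across the
ensemble rather than trusting any single fit.

## The model

Each species is a state $\bar x_i \in [0,1]$ (activities are normalized).
The influence of a regulator on its target passes through a normalized Hill
transfer

$$H(x) = \frac{x^n}{x^n + k^n}(1 + k^n),$$

which fixes $H(0)=0$ and $H(1)=1$ for every exponent $n \ge 1$ and
half-saturation $k \in (0,1]$: regulator activity and drive live on the same
unit scale. A node with $N$ regulators combines their transfers by
multilinear interpolation of a Boolean truth table: with one weight
$w \in [0,1]$ per Boolean corner,

$$\bar B_i = \sum_{x \in \{0,1\}^N} w_x \prod_k \bigl[x_k H_k + (1-x_k)(1-H_k)\bigr].$$

The corner products form a partition of unity, so $\bar B_i$ is a convex
combination of the weights and stays in $[0,1]$; at saturated inputs it
reproduces the truth table exactly, which is why binary weight assignments
realize all 16 two-input Boolean gates (an AND is $w_{11}=1$, an OR sets
every corner with an active input to 1, and so on). Dynamics are first-order
relaxation toward the gate drive,

$$\dot{\bar x}_i = (\bar B_i - \bar x_i)/\tau_i,$$

with $\tau_i$ the species' lifetime in data time units. Stimulus (ligand)
nodes are clamped constants. Two inhibitor mechanisms are supported:
`"node"` mode multiplies the target's derivative by $(1-\mathrm{inh})$ —
a fully inhibited species is frozen — and `"downstream"` mode damps the
$x^n$ term of the inhibited species inside its targets' Hill transfers. In
the downstream form we apply $(1-\mathrm{inh})$ to $x^n$ in both numerator
and denominator and keep the $(1+k^n)$ normalization outside, so zero
inhibition reduces exactly to the plain transfer and full inhibition
silences the edge; other groupings break one of those two limits.

## The workflow

1. **Mutual information.** Signals are pooled across all experiments and
   time points, discretized (equal-frequency bins,
   $\lceil\sqrt{N}\rceil$ by default for $N$ pooled samples), and the
   plug-in MI in bits is computed for every pair. Stimulus treatments enter
   as pseudo-signals so ligand nodes can be sampled as parents. When
   inhibitors are present a second MI matrix is computed on data where
   inhibited species are scaled by $(1-\mathrm{inh})$ in their inhibited
   conditions, and the elementwise maximum of the two matrices is used —
   an inhibitor can mask a regulator's influence in the raw data.
2. **Scaffold sampling.** For each target node, up to `max_indegree`
   distinct parents are drawn without replacement with probability
   proportional to MI. Scaffolds are deliberately dense and diverse;
   false positives are left for the reduction step.
3. **Training.** All Hill parameters, gate weights and lifetimes are fitted
   at once by minimizing the pooled squared error between simulated and
   measured trajectories, within bounds, using a seeded
   differential-evolution search plus a bounded quasi-Newton polish.
   Where every regulator of a node is itself observed, a *teacher-forced
   pre-fit* first fits that node alone against the interpolated measured
   regulator trajectories; the assembled node-wise solution seeds the joint
   population. This warm start is what makes desk-scale global fits
   reliable — the joint landscape has many basins that differ in one
   node's gate.
4. **Reduction.** Active edges are visited in seeded random order; removing
   an edge is implemented exactly as forcing its Hill term to zero, which
   collapses the weight array to the regulator-off slice. The remaining
   parameters are refitted by a warm-started local search
   (coordinate-wise adaptive hill-climbing with a quasi-Newton finisher),
   and the deletion is kept iff the AIC
   $2K + 2n\ln(F/n)$ strictly decreases, where $K$ counts the active
   parameters ($2N$ Hill parameters, $2^N$ weights and one lifetime per
   node with $N$ active regulators). Incumbent and candidate are scored at
   the same solver tolerance so integration error cancels from the
   comparison.
5. **Ensemble prediction.** Member trajectories are combined per time point
   and signal into the median and empirical central percentile bands
   (20/60/95% by default, linear interpolation between order statistics).
   Members whose integration fails are dropped from that experiment only.
   Edge confidences are the fraction of members containing the edge, and
   feed precision-recall evaluation against a reference network.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `max_indegree` | 3 | parents sampled per node; decision variables grow as $2^N$, keep small |
| `n_models` | 10 | ensemble size; skill converges quickly with size (see `bootstrap_ensemble_curve()`) |
| `n` bounds | [1, 10] | Hill exponent, quasi-linear to switch-like |
| `k` bounds | [0.01, 0.99] | half-saturation on the normalized activity scale |
| `tau` bounds | [0.01, 50] | lifetime in data time units |
| `inh_strength` | 0.9 | inhibition applied when a MIDAS inhibitor flag is on |
| `budget` | 6000 | objective evaluations for the joint global search |
| `noise_sd` | 0.05 | synthetic measurement noise (normalized units) |

Data are normalized by dividing every value of a signal by that signal's
maximum across all training conditions and time points; held-out data are
scaled by the *training* maxima (the model's unit scale is defined by the
training set; scaling held-out data by its own maxima would silently change
units between fitting and validation).

## Numerical choices

* The integrator is an adaptive Dormand–Prince RK45 with `rtol = 1e-6`,
  `atol = 1e-8` for reported simulations. The logic-ODE right-hand side is
  smooth and at most mildly stiff within the default lifetime bounds, which
  this scheme handles at a fraction of the cost of an implicit method.
  States are clipped to $[0,1]$ at output only; regulator activities are
  clamped to $[0,1]$ inside the Hill transfer to keep non-integer powers
  defined against solver-scale excursions.
* During population search the solver runs at a relaxed tolerance
  (`1e-4`, or as requested); the final polish and all reported objectives
  use the requested tolerance. AIC comparisons always use one tolerance on
  both sides.
* Initial states come from the $t=0$ measurements where available, else 0;
  stimulus nodes start and stay at their experimental level.
* A failed integration inside the objective yields a large finite penalty
  (`1e10`), never an exception, so stochastic optimizers keep moving.
* $F=0$ (attainable on noise-free synthetic fits) is floored at machine
  epsilon inside the AIC logarithm.
* Even-sized ensembles use midpoint medians; percentile bands interpolate
  linearly between order statistics.
* Precision-recall areas accumulate step-wise (each recall increment
  contributes that threshold's precision, no interpolation — trapezoids are
  optimistic for PR curves); ROC areas use the trapezoid rule; tied scores
  share one threshold. Evaluation is over *directed* edges: a prediction in
  the wrong direction is a false positive (a `symmetrize` flag exists for
  comparing undirected methods).

## The synthetic benchmark generator

`generate_truth_model()` builds a connected cascade: ligand nodes first,
every species regulated by its immediate predecessor plus up to
`max_indegree - 1` further upstream parents, each node realizing a named
gate (activator, NOT, AND, OR) through binary corner weights, with moderate
Hill parameters ($n \in [1.5,4]$, $k \in [0.3,0.7]$) and lifetimes
($\tau \in [0.5,3]$) well inside the training bounds. Designs cross ligand
levels (on/off by default, off/low/high supported) with one-at-a-time node
inhibition, the typical layout of kinase-inhibitor screens.
`simulate_dataset()` adds i.i.d. Gaussian noise ($\sigma = 0.05$ by
default, the scale of replicate variation in normalized protein-array data)
and clips to $[0,1]$ so downstream normalization and the unit-box model
assumption hold — a deliberate deviation from a purely additive noise
model, which could leave the box.

What the generator emulates: bounded-in-degree directed scaffolds, logic-ODE
dynamics, ligand-by-inhibitor designs, additive measurement noise, partial
observation. What it does not: receptor-level mass-action detail,
time-varying treatments within an experiment, correlated or
intensity-dependent noise, unmeasured confounding species. Tests that pass
on these benchmarks therefore establish internal consistency of the
machinery and recovery under the stated conditions, not performance on any
particular biological dataset.

## Problem sizes used in the test suite

The package's statistical checks run at desk scale, chosen so the full
suite completes on a single CPU: recovery experiments use 6-node,
2-stimulus cascades with in-degree bound 2, full on/off ligand crosses with
single-node inhibitions, 6 sampling times on $[0,10]$, training budgets of
a few thousand objective evaluations per model, and ensembles of 10 models
over 10 seeded replicates. For the noisy ensemble benchmark the lifetime
lower bound is raised to 0.1 time units: with unit sampling spacing, a
species relaxing faster than a tenth of the first sampling interval is
indistinguishable from an instantaneous one, and excluding that
unidentifiable sliver of parameter space keeps the search in the regime the
data can actually constrain (it also avoids needlessly stiff candidate
integrations).

## Known limitations

* Reduction decisions on *noise-free* data are delicate: as $F \to 0$ the
  AIC's $n\ln(F/n)$ term diverges, so accepting a deletion requires the
  warm-started refit to come within a fraction of a percent of the
  incumbent's objective. The teacher-forced refresh of the affected node
  (`refresh = TRUE`) exists for exactly this regime.
* MI estimated from a few dozen pooled samples ranks candidate parents
  weakly; scaffolds then miss true edges and no amount of fitting recovers
  them. This mirrors the intrinsic difficulty of data-driven inference at
  small sample sizes — the ensemble over many scaffolds is the mitigation,
  not a cure.
* The scatter-search metaheuristic of the original formulation is replaced
  by an in-package differential-evolution engine satisfying the same
  contract (seeded, bounded, budgeted, monotone best-objective trace);
  scatter-search-style recombination could be swapped in without touching
  any interface.
* Concurrency is deliberately absent from the package core; per-model work
  is independent, and per-model seeds are derived deterministically from
  the master seed so any external parallel scheduler reproduces the
  sequential results.
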