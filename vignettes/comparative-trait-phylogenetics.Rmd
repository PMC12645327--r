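---
title: "Comparative Bayesian phylogenetics for binary cultural traits"
author: "traitphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative Bayesian phylogenetics for binary cultural traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitphylo)
```

## The problem

Languages, technologies and other cultural traditions are transmitted with
modification, so their histories can be reconstructed with the same
machinery used for molecular phylogenetics. The data are binary
presence/absence characters — lexical cognate sets across languages, or
functional attributes of artefacts such as looms — and the questions are
comparative: do two trait systems carried by the same populations share one
evolutionary tree, how fast do different classes of characters change, and
how much of one system's variation does the other system's phylogeny
explain?

`traitphylo` implements the full pipeline: a binary covarion substitution
model with strict and relaxed lognormal clocks, birth–death (BD) and
fossilised birth–death (FBD) tree priors with hard node- and tip-age
calibrations, Metropolis–Hastings MCMC over time trees, majority-rule
consensus summarisation, stepping-stone marginal likelihoods with
Kass–Raftery Bayes-factor interpretation, and a congruence suite (Mantel
tests on patristic distances, PCA trait projection, Blomberg's K averaged
over posterior trees). A forward simulator generates trees and matrices
with the same statistical structure, so every stage is testable without
any external data.

## The substitution model

Each character evolves on the tree as a four-state continuous-time Markov
chain: visible states $\{0, 1\}$ (absent/present) crossed with hidden rate
categories $\{\text{fast}, \text{slow}\}$. Within the fast category the
visible state flips at relative rate 1 scaled by the target frequency
$(\pi_0, \pi_1)$; the slow category is damped by $\alpha \in (0, 1]$; the
hidden category toggles at symmetric rate $s$ without changing the visible
state. Hidden categories are equally frequent at stationarity and the
stationary visible marginals equal $(\pi_0, \pi_1)$. The generator is
rescaled so one unit of branch length × clock rate equals `overallRate`
expected visible substitutions at stationarity — this keeps clock rates
interpretable (substitutions per unit time) and node ages identifiable.

Two exact reductions anchor the implementation: at $\alpha = 1$ the visible
process is the plain two-state chain for every $s$, and at $s = 0$ the
generator is block diagonal (frozen categories). The pruning likelihood is
verified against exhaustive hidden-state enumeration on all trees with up
to four tips across a parameter grid at $10^{-10}$.

Missing entries (`?`) are treated as full ambiguity — an all-ones tip
partial — the conventional treatment. Characters are stored as raw
presence/absence with no ascertainment correction; whether cognate data
warrant one is an open modelling question, and the likelihood contract
(weighting = replication) is agnostic to it.

## Weights and partitions

Per-character weights multiply log-likelihood contributions; an integer
weight $w$ is exactly equivalent to replicating the character $w$ times
(tested at $10^{-12}$). This supports inverse-dependency weighting of
hierarchical characters (levels 1–4 weighted 8/4/2/1) and makes subsetting
a special case (weight zero).

Partition schemes give character groups (parts of speech, or dependency
levels) their own rate multipliers. Multipliers are renormalised to
character-weighted mean one inside the likelihood, which separates
between-partition heterogeneity from the global clock rate; the sampler
proposes unnormalised rates with exponential priors, and only the
normalised values are reported.

## Tree priors, calibrations and the time scale

The BD/FBD density is the telescoped product of per-lineage factors
$q(t)$ with extinction-survival probabilities $p_0(t)$ (the standard
$c_1, c_2$ parameterisation with birth rate $\lambda$, death rate $\mu$,
extant sampling $\rho$ and fossil sampling $\psi$). Conventions, chosen
once and used consistently by the density, the sampler and the simulator:

* densities are conditional on the root age, and each root lineage must
  leave at least one sampled descendant (the $(1 - p_0)^{-2}$ term);
* the root age itself carries a proper uniform prior on $(0,
  \texttt{rootMax})$;
* fossils are terminal tips sampled with removal; sampled ancestors on
  internal branches are not modelled (the data this design targets have
  fossil tips only, e.g. one extinct language and one archaeological
  loom);
* parameter-free combinatorial constants are omitted throughout — they
  cancel in MCMC and in Bayes factors.

With $\mu = 0$, $\rho = 1$ the density collapses to the conditioned Yule
form $\lambda^{n-2} e^{-\lambda L}$ ($L$ = total branch length), which the
tests verify, as well as the FBD→BD reduction at $\psi = 0$.

Calibrations are uniform hard bounds on MRCA ages or fossil tip ages.
Calendar inputs declare their unit; CE is converted as
$\mathrm{BP} = 1950 - \mathrm{CE}$ (radiocarbon convention, configurable
epoch), because silently mixing CE and BP is the easiest way to ruin an
analysis.

The forward simulator draws the root age from the prior times the squared
survival factor (grid inverse-CDF), grows two birth–death subtrees
forward, $\rho$-samples the extant tips and rejects until exactly the
requested number survive with both root lineages sampled. This makes the
simulator and the MCMC target *the same distribution*, so prior-sampling
agreement is an exact test, not an approximation: a data-free chain's
root-age sample is compared with 2000 forward simulations by a KS test.

## The sampler

The state holds the tree (parent pointers + node ages), covarion
parameters, clock, partition rates and BD parameters, with cached log
likelihood and prior (optionally re-verified from scratch every k steps).
Operators: uniform node-age slides within their age windows, root-age and
whole-tree scalers, narrow exchange, an age-windowed
subtree-prune-regraft (the regraft height is drawn uniformly in the
feasible window, with the window-length Hastings ratio), fossil-tip age
draws within calibration bounds, multiplicative scalers and reflected
random walks for scalar parameters, and a rate×time ridge move that
stretches all internal ages by $f$ while dividing the clock rate by $f$
(Jacobian $f^{\,n_{\text{int}}-1}$). The ridge move matters: rate and tree
depth are strongly confounded in clock models, and without it the
effective sample size of the rate can be an order of magnitude lower.
Operator scales adapt toward 30% acceptance during burn-in only, so
detailed balance holds for every retained sample.

Correctness is checked end to end on a 3-tip problem where the posterior
over (topology, two node ages) is computed by dense numerical integration:
the MCMC's joint distribution agrees within total-variation distance 0.05,
and the topology frequencies match to three decimals.

Starting trees come from average-linkage clustering of Hamming distances
when the data allow it, otherwise from random calibration-compatible
sequential joins (retried up to 100 times).

Relaxed clocks use continuous per-branch lognormal multipliers
(mean-one parameterisation, $\mu_{\log} = -\sigma^2/2$) attached to child
nodes, each sampled in the MCMC along with $\sigma$; discretised rate
categories are an optimisation we deliberately avoid.

## Marginal likelihoods and the shared-tree Bayes factor

Stepping-stone sampling runs power-posterior chains at $\beta$ values
placed at Beta(0.3, 1) quantiles (dense near 0) and accumulates
$\log \mathrm{ML} = \sum_k \log \overline{\exp((\beta_{k+1} - \beta_k)
\ell)}$. A constant likelihood gives the exact answer for any number of
stones; on a one-parameter fixed-tree problem the estimate agrees with
dense quadrature within three standard errors. The reported standard error
is a within-step bootstrap over importance weights — cheaper than
independent replicate runs and calibrated enough for interpretation;
replicate variance shrinks as stones are added, which the tests check
directly.

The shared-vs-separate phylogeny comparison restricts both matrices to the
mapped shared taxa, relabels the second matrix to its partners, and
estimates three marginal likelihoods under identical settings (binary
covarion, strict clock, homogeneous rate): merged matrix on one tree
(scenario A) and each matrix alone (summed, scenario B).
$\log \mathrm{BF} = \log \mathrm{ML}_B - \log \mathrm{ML}_A$; thresholds
1/3/5 on the natural-log scale give the Kass–Raftery categories
(negligible/positive/strong/decisive), signed by the favoured scenario.

## Congruence statistics

*Mantel*: the statistic is the raw cross-product
$z = \sum_{i<j} D_a[i,j]\, D_b[i,j]$ (scale-dependent, so the Pearson
correlation $r$ over the same pairs is reported alongside); the null
permutes rows and columns of $D_b$ simultaneously and the one-tailed
p-value for positive association is $(1 + \#\{z_\pi \ge z\}) /
(1 + B)$. Permutation defaults to $B = 999$, whose p-floor is 0.001. The
seeded permutation p agrees with exhaustive enumeration at 4–5 taxa and
the type-I error is calibrated (within [0.03, 0.07] at $\alpha = 0.05$
over 1000 null pairs). Distance matrices come either from consensus trees
or from posterior averages: subsample $n$ trees, depth-normalise each
(so deeper trees get no extra weight), prune to the shared taxa, average.

*PCA + Blomberg's K*: binary tip data are mean-imputed, column-centred and
projected on the first right singular direction; the sign convention makes
the largest-magnitude score positive (ties broken by taxon label), which
is deterministic and invariant under character reordering — a sign
anchored on loadings is not well-defined when loadings tie. K is the ratio
of the observed $\mathrm{MSE}_0/\mathrm{MSE}$ (about the phylogenetic GLS
mean, with the tree's tip covariance) to its Brownian-motion expectation;
it is computed directly from the tip covariance so non-ultrametric
consensus trees need no adjustment, averaged over posterior trees, and
tested by tip shuffles applied identically across trees. On
Brownian-motion data the mean K over 200 replicates on a 32-tip tree sits
in [0.8, 1.2]; K is exactly invariant under affine transforms of the trait.

## The synthetic-data generator

The generator is first-class code, and its defaults are the package's
study conditions:

* trees: birth–death with $\lambda = 1.5$, $\mu = 0.25$, $\rho = 1$ and a
  uniform root-age prior capped at 3 (time in arbitrary units; depths
  then fall around 1–2.5), 16–20 extant taxa for inference experiments;
* characters: covarion with equal visible frequencies, $\alpha = 0.5$,
  $s = 0.5$, overall rate 0.2 — about 0.2–0.5 expected substitutions per
  character root-to-tip. Binary characters saturate quickly: rates much
  above ~0.5 per tree depth destroy topological signal (we verified this
  with independent distance-based reconstruction), and rates far below
  0.05 leave too few variable characters; 0.2 is the informative middle
  of that range and the regime clock-based cultural datasets occupy;
* dataset sizes mirror the motivating data: a few hundred characters
  (e.g. 300 per side for paired comparisons; 216-character
  structure/patterning-style fixtures; 100 characters per dependency
  level with multipliers 0.5/1/2/2 for rate-recovery experiments);
* fossil tips are attached at uniform feasible points with ages drawn
  from declared windows (a 4400–4600 BP-style window in rescaled units),
  which decorates the tree rather than sampling the exact FBD
  distribution — adequate for exercising fossil handling, and stated as
  such;
* hierarchical dependencies: each level-k character may be clamped absent
  wherever its randomly assigned level-(k−1) parent is absent. The clamp
  is applied at the tips, which enforces the defining invariant (no child
  present where its parent is absent) without modelling the full joint
  process;
* punctuated change: a fraction $f$ of each branch's expected change is
  concentrated in a burst at the branch origin, implemented as an
  exponential extra duration with mean $f\,t$ shared across characters
  plus a gradual $(1-f)\,t$ remainder. The shared draw is what makes
  per-branch change counts overdispersed — a per-character independent
  burst would be statistically indistinguishable from gradual evolution
  by the Markov property. Expected change is conserved for every $f$, and
  $f = 0$ consumes no random numbers, so it reduces bit-identically to
  the gradual simulator under a shared seed.

What the simulator does *not* emulate: borrowing/contact networks,
ascertainment bias in cognate coding, non-independence beyond the
presence/absence clamp, and rate variation across characters beyond the
covarion's two categories plus level multipliers. Passing tests therefore
demonstrate internal correctness and statistical calibration under the
model's own assumptions, not robustness to real-data violations of them.

## Problem sizes and calibration experiments

The test suite's simulation experiments use desk-scale sizes chosen as the
smallest that make the statistical assertions sharp: coverage of the
clock-rate credible interval and rank-order recovery of the four level
multipliers use 16 taxa × 400–500 characters with 8000-step chains over
20 replicates each (truth drawn from the sampler's own prior, so nominal
coverage is exact up to Monte Carlo error); Bayes-factor sign recovery
uses 20 taxa × 300 characters per side with 6 stepping stones × 900 steps
over 10 seeds per scenario; end-to-end consensus recovery uses 16 taxa ×
400 characters with 12000-step chains over 10 seeds. The prior-sampling
check compares 2000 forward simulations with a 200,000-step data-free
chain at 8 taxa.

## Numerical choices

* Likelihood: compiled pruning over 4×`nChar` partial matrices, with
  per-node rescaling triggered only when the partial maximum drops below
  1e-150; transition matrices come from the symmetrised eigendecomposition
  of the (reversible) covarion generator, with a scaling-and-squaring
  series fallback for general generators.
* Consensus: clades at exactly the threshold are included ("50% or more");
  among mutually incompatible clades at identical frequency the
  lexicographically smallest tip set wins — determinism over cleverness.
  Consensus node ages are the mean MRCA age over the trees containing the
  clade (hence generally non-ultrametric); a parent mean occasionally
  falls below a child mean over different tree subsets, in which case the
  parent is clamped up to keep branch lengths non-negative. Mean rather
  than median heights is an arbitrary but documented choice.
* ESS: initial-positive-sequence autocovariance truncation, capped at n;
  constant traces warn and report n.
* HPD: shortest interval containing the requested mass of the sorted
  sample.
* Degenerate inputs fail loudly: empty character selections, zero-depth
  trees, constant traits for K, critical birth–death parameters
  ($c_1 = 0$), calibrations on unknown taxa.

## Limitations

Sampled ancestors, multistate and Dollo models, across-site gamma rates,
partial Mantel tests controlling for geography, and any inference of
evolutionary *mode* (gradual vs punctuated) are out of scope — the
generator can produce both regimes, but the package deliberately ships no
mode test. Marginal-likelihood estimates at desk-scale chain lengths carry
a few log units of noise; Bayes-factor *signs* at a few hundred characters
are robust (the tests demand 9/10 seed agreement), but magnitudes should
be read with their standard errors.

## A worked sketch

```{r example, eval = FALSE}
library(traitphylo)
sim <- simulatePairedDatasets(20, 300, sameTree = TRUE,
  model = CovarionModel(overallRate = 0.2),
  treePrior = BirthDeathParams(1.5, 0.25, 1), rootMax = 3, seed = 1)
ps <- runMcmc(sim$a, CovarionModel(overallRate = 0.2),
  treePrior = BirthDeathParams(1.5, 0.25, 1),
  chainLength = 12000, sampleEvery = 10, seed = 12,
  hyper = list(rootMax = 3))
cons <- majorityConsensus(ps@trees)
cladeRecovery(sim$treeA, cons)
```

The package-level orchestration (`pipelineSimulate`, `pipelineInfer`,
`pipelineCompare`, `pipelineBayesFactor`) wraps the same functions behind
a single declarative YAML config with one root seed, and
`scripts/acceptance.R` reruns the whole comparative analysis from scratch.
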