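# traitphylo

Bayesian phylogenetic inference and cross-phylogeny comparison for binary
presence/absence trait matrices — the kind of data produced when lexical
cognate sets are coded across languages, or when the functional attributes
of artefacts (loom components, patterning devices) are coded across
material-culture traditions. The package is aimed at cultural-evolution
and historical-linguistics researchers who want BEAST-style inference plus
a quantitative answer to the comparative question: *did two trait systems
carried by the same populations evolve along one phylogeny or two?*

## What it implements

**Substitution model.** The binary covarion: visible states
{absent, present} × hidden categories {fast, slow}. Within a category the
visible state flips at relative rate 1 (fast) or α (slow) scaled by the
stationary frequencies (π₀, π₁); categories toggle at symmetric rate *s*.
The generator is normalised so branch length × clock rate is measured in
expected visible substitutions. Strict and relaxed (mean-one lognormal
branch-multiplier) clocks.

**Tree priors.** Birth–death and fossilised birth–death densities in the
standard q(t)/p₀(t) telescoped form (parameters λ, μ, ρ, ψ), conditioned
on the root age with survival of both root lineages, fossils as terminal
tips; hard uniform calibrations on MRCA ages and fossil tip ages, with
explicit CE↔BP unit conversion (BP = 1950 − CE).

**Inference.** Metropolis–Hastings MCMC over topology, node ages, fossil
tip ages, covarion, clock, partition and tree-prior parameters; weighted
and partitioned likelihoods (integer weight w ≡ replicating a character w
times; partition rate multipliers renormalised to weighted mean one);
majority-rule consensus with percentage clade supports and mean node ages;
MRCA age posteriors with HPD intervals; ESS diagnostics.

**Model comparison.** Stepping-stone marginal likelihoods (power
posteriors at Beta(0.3, 1) quantiles) and the shared-vs-separate phylogeny
log Bayes factor, interpreted on the Kass–Raftery scale (thresholds 1/3/5
in natural log; positive favours separate phylogenies).

**Congruence suite.** Mantel tests (raw cross-product z with Pearson r,
simultaneous row/column permutations) on consensus-tree or
posterior-averaged, depth-normalised patristic distances; PCA projection
of binary tip data; Blomberg's K computed from the tip covariance
(non-ultrametric trees included) and averaged over posterior trees with a
tip-shuffle permutation test.

**Synthetic data.** Forward birth–death tree simulation conditioned on the
sampled tip count (exactly matching the prior the sampler targets), exact
Gillespie simulation of covarion characters, hierarchical character
dependencies with an absence clamp, fossil tips in declared age windows,
and a punctuated-change regime (burst at branch origin) that reduces
bit-identically to the gradual one at burst fraction 0.

## A worked example

Simulate two 300-character datasets on one 20-taxon tree, infer both
posteriors, and ask whether the package can tell they share a phylogeny:

```r
library(traitphylo)
sim <- simulatePairedDatasets(20, 300, sameTree = TRUE,
  model = CovarionModel(overallRate = 0.2),
  treePrior = BirthDeathParams(1.5, 0.25, 1), rootMax = 3, seed = 1)

psA <- runMcmc(sim$a, CovarionModel(overallRate = 0.2),
  treePrior = BirthDeathParams(1.5, 0.25, 1),
  chainLength = 12000, sampleEvery = 10, seed = 12,
  hyper = list(rootMax = 3))
psB <- runMcmc(sim$b, CovarionModel(overallRate = 0.2),
  treePrior = BirthDeathParams(1.5, 0.25, 1),
  chainLength = 12000, sampleEvery = 10, seed = 13,
  hyper = list(rootMax = 3))

consA <- majorityConsensus(psA@trees)
cladeRecovery(sim$treeA, consA)
#> [1] 0.8888889

mantelTest(patristicMatrix(consA, taxa(sim$a)),
           patristicMatrix(majorityConsensus(psB@trees), taxa(sim$b)),
           999, seed = 2)
#> Mantel test: z = 1170, r = 0.9418, p = 0.001 (999 permutations)

kOverPosterior(psA@trees[1:300], firstPrincipalComponent(sim$b),
               permutations = 999, seed = 3,
               provenance = "PC1 of dataset b")
#> Blomberg's K (PC1 of dataset b): mean K = 3.6242 over 300 trees, p = 0.001

sharedTreeBayesFactor(sim$a, sim$b,
  data.frame(a = taxa(sim$a), b = taxa(sim$b)),
  model = CovarionModel(overallRate = 0.2),
  treePrior = BirthDeathParams(1.5, 0.25, 1),
  steps = 6, chainLength = 900, sampleEvery = 3, seed = 4,
  hyper = list(rootMax = 3))
#> log ML shared tree (A): -5396.13 (sd 0.53)
#> log ML separate trees (B): -5445.35 (sd 0.87)
#> log BF (B - A): -49.21 -> decisive evidence for a shared phylogeny (A)
```

Reading the output: the consensus recovers 89% of the true clades; the two
independently inferred consensus trees give strongly correlated patristic
distances (r = 0.94 at the 999-permutation p-floor of 0.001); the first
principal component of dataset b carries strong phylogenetic signal on
dataset a's posterior trees (mean K = 3.6 ≫ 1); and the Bayes factor
decisively — and correctly — favours a single shared phylogeny. Datasets
simulated on two different trees flip the Bayes factor's sign by hundreds
of log units.

Config-driven orchestration (`pipelineSimulate`, `pipelineInfer`,
`pipelineCompare`, `pipelineBayesFactor`) runs the same stages from a
single YAML file with one root seed; `inst/cli/traitphylo` is a thin
command-line wrapper over them.

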