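#' @useDynLib traitphylo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats runif rexp rnorm rlnorm rbinom sd quantile median cor
#'   prcomp approx optimize setNames aggregate integrate var
#' @importFrom utils head tail read.csv write.csv
#' @importFrom tools md5sum
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))
setClassUnion("characterOrNULL", c("character", "NULL"))

#' Annotated binary trait matrix
#'
#' Taxa-by-character presence/absence data with an explicit missing state and
#' optional per-character annotations: a dependency level (1-4), a category
#' label (e.g. part of speech, or structure vs. patterning), and a positive
#' weight that multiplies the character's log-likelihood contribution.
#'
#' @slot states integer matrix, taxa in rows and characters in columns;
#'   entries 0 (absent), 1 (present) or \code{NA} (missing). Row names are
#'   taxon labels, column names are character ids.
#' @slot levels optional integer vector (one per character) in 1..4.
#' @slot categories optional character vector, one per character.
#' @slot weights numeric vector of positive per-character weights.
#' @export
setClass("TraitMatrix",
  representation(states = "matrix", levels = "integerOrNULL",
    categories = "characterOrNULL", weights = "numeric"))

setValidity("TraitMatrix", function(object) {
  st <- object@states
  msg <- character()
  if (is.null(rownames(st)) || is.null(colnames(st)))
    msg <- c(msg, "states must have taxon row names and character column names")
  else {
    if (anyDuplicated(rownames(st)))
      msg <- c(msg, "duplicate taxon labels")
    if (anyDuplicated(colnames(st)))
      msg <- c(msg, "duplicate character ids")
  }
  bad <- !(st %in% c(0L, 1L, NA))
  if (any(bad)) msg <- c(msg, "states must be 0, 1 or NA")
  nc <- ncol(st)
  if (!is.null(object@levels)) {
    if (length(object@levels) != nc)
      msg <- c(msg, "levels must have one entry per character")
    else if (!all(object@levels %in% 1:4))
      msg <- c(msg, "levels must be integers in 1..4")
  }
  if (!is.null(object@categories) && length(object@categories) != nc)
    msg <- c(msg, "categories must have one entry per character")
  if (length(object@weights) != nc)
    msg <- c(msg, "weights must have one entry per character")
  else if (any(!is.finite(object@weights)) || any(object@weights <= 0))
    msg <- c(msg, "weights must be positive and finite")
  if (length(msg)) msg else TRUE
})

#' Partition scheme over characters
#'
#' Disjoint groups of character ids with per-group rate multipliers. When used
#' in a likelihood the multipliers are renormalised to character-weighted mean
#' one, which separates between-partition rate heterogeneity from the global
#' clock rate.
#'
#' @slot name label for the scheme.
#' @slot groups named list of character-id vectors (disjoint, jointly covering
#'   the characters under analysis).
#' @slot rateMultipliers named positive numeric, one per group.
#' @export
setClass("PartitionScheme",
  representation(name = "character", groups = "list",
    rateMultipliers = "numeric"))

setValidity("PartitionScheme", function(object) {
  msg <- character()
  ids <- unlist(object@groups, use.names = FALSE)
  if (anyDuplicated(ids)) msg <- c(msg, "partition groups must be disjoint")
  if (length(object@rateMultipliers) != length(object@groups))
    msg <- c(msg, "one rate multiplier per group required")
  if (any(object@rateMultipliers <= 0) || any(!is.finite(object@rateMultipliers)))
    msg <- c(msg, "rate multipliers must be positive and finite")
  if (is.null(names(object@groups)))
    msg <- c(msg, "groups must be named")
  if (length(msg)) msg else TRUE
})

#' Binary covarion substitution model
#'
#' Two visible states (absent/present) crossed with hidden fast/slow rate
#' categories. Within a category substitution runs at relative rate 1 (fast)
#' or \code{alpha} (slow), scaled by the visible stationary frequencies;
#' hidden-category switching occurs at symmetric rate \code{switchRate} and
#' preserves the visible state. The generator is normalised so that one unit
#' of (branch length x clock rate) equals \code{overallRate} expected visible
#' substitutions at stationarity.
#'
#' @slot freq numeric length-2 simplex: stationary frequencies of
#'   (absent, present).
#' @slot alpha slow/fast rate ratio in (0, 1].
#' @slot switchRate hidden-category switch rate, >= 0.
#' @slot overallRate expected visible substitutions per unit time, > 0.
#' @export
setClass("CovarionModel",
  representation(freq = "numeric", alpha = "numeric",
    switchRate = "numeric", overallRate = "numeric"),
  prototype(freq = c(0.5, 0.5), alpha = 0.5, switchRate = 0.5,
    overallRate = 1))

setValidity("CovarionModel", function(object) {
  msg <- character()
  if (length(object@freq) != 2 || any(object@freq <= 0) ||
      abs(sum(object@freq) - 1) > 1e-8)
    msg <- c(msg, "freq must be a positive length-2 simplex")
  if (object@alpha <= 0 || object@alpha > 1)
    msg <- c(msg, "alpha must lie in (0, 1]")
  if (object@switchRate < 0) msg <- c(msg, "switchRate must be >= 0")
  if (object@overallRate <= 0) msg <- c(msg, "overallRate must be > 0")
  if (length(msg)) msg else TRUE
})

#' Clock model (strict or relaxed lognormal)
#'
#' Strict: every branch evolves at \code{meanRate}. Relaxed: branch rates are
#' \code{meanRate} times i.i.d. mean-one lognormal multipliers with log-scale
#' standard deviation \code{stdevLog}.
#'
#' @slot kind "strict" or "relaxed".
#' @slot meanRate substitutions per unit time, > 0.
#' @slot stdevLog standard deviation of log branch-rate multipliers
#'   (relaxed only), >= 0.
#' @export
setClass("ClockModel",
  representation(kind = "character", meanRate = "numeric",
    stdevLog = "numeric"),
  prototype(kind = "strict", meanRate = 1, stdevLog = 0))

setValidity("ClockModel", function(object) {
  msg <- character()
  if (!object@kind %in% c("strict", "relaxed"))
    msg <- c(msg, "kind must be 'strict' or 'relaxed'")
  if (object@meanRate <= 0) msg <- c(msg, "meanRate must be > 0")
  if (object@stdevLog < 0) msg <- c(msg, "stdevLog must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Birth-death / fossilised birth-death parameters
#'
#' @slot lambda birth rate per lineage-time, > 0.
#' @slot mu death rate per lineage-time, >= 0.
#' @slot rho extant sampling fraction in (0, 1].
#' @slot psi fossil sampling rate per lineage-time, >= 0 (0 reduces the
#'   fossilised birth-death process to plain birth-death).
#' @export
setClass("BirthDeathParams",
  representation(lambda = "numeric", mu = "numeric", rho = "numeric",
    psi = "numeric"),
  prototype(lambda = 1, mu = 0, rho = 1, psi = 0))

setValidity("BirthDeathParams", function(object) {
  msg <- character()
  if (object@lambda <= 0) msg <- c(msg, "lambda must be > 0")
  if (object@mu < 0) msg <- c(msg, "mu must be >= 0")
  if (object@rho <= 0 || object@rho > 1) msg <- c(msg, "rho must lie in (0, 1]")
  if (object@psi < 0) msg <- c(msg, "psi must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Age-calibration constraint
#'
#' Uniform hard bounds (years BP, or any consistent time unit) either on the
#' MRCA age of a taxon set or on the age of a single (fossil) tip.
#'
#' @slot kind "mrca" or "tip".
#' @slot taxa taxon labels (one label for kind "tip").
#' @slot lower,upper bounds with 0 <= lower < upper.
#' @export
setClass("Calibration",
  representation(kind = "character", taxa = "character",
    lower = "numeric", upper = "numeric"))

setValidity("Calibration", function(object) {
  msg <- character()
  if (!object@kind %in% c("mrca", "tip"))
    msg <- c(msg, "kind must be 'mrca' or 'tip'")
  if (object@kind == "tip" && length(object@taxa) != 1)
    msg <- c(msg, "tip calibration takes exactly one taxon")
  if (length(object@taxa) < 1) msg <- c(msg, "taxa must be non-empty")
  if (!(object@lower >= 0 && object@lower < object@upper))
    msg <- c(msg, "bounds must satisfy 0 <= lower < upper")
  if (length(msg)) msg else TRUE
})

#' Posterior sample from the phylogenetic MCMC
#'
#' Thinned post-burn-in states: sampled time trees with matching rows of the
#' parameter trace (log posterior, log likelihood, log prior, substitution,
#' clock, partition and tree-prior parameters), plus per-operator acceptance
#' statistics.
#'
#' @slot trees list of \code{ape::phylo} time trees.
#' @slot trace data.frame, one row per retained state.
#' @slot sampleEvery thinning interval (in MCMC steps).
#' @slot burnin number of discarded initial steps.
#' @slot seed integer seed the chain was run under.
#' @slot acceptance named acceptance rates per operator.
#' @export
setClass("PhyloPosterior",
  representation(trees = "list", trace = "data.frame",
    sampleEvery = "integer", burnin = "integer", seed = "integer",
    acceptance = "numeric"))

setValidity("PhyloPosterior", function(object) {
  if (length(object@trees) != nrow(object@trace))
    "trees and trace must have matching lengths" else TRUE
})

#' Stepping-stone marginal-likelihood estimate
#'
#' @slot logML estimated log marginal likelihood.
#' @slot sd standard error (within-step bootstrap across importance weights).
#' @slot betas power-posterior schedule (ordered 0 -> 1).
#' @slot stepESS effective sample size of the importance weights per step.
#' @export
setClass("MarginalLikelihoodEstimate",
  representation(logML = "numeric", sd = "numeric", betas = "numeric",
    stepESS = "numeric"))

#' Shared-vs-separate phylogeny Bayes factor
#'
#' Scenario A: both matrices evolved on one shared tree (merged analysis).
#' Scenario B: each matrix evolved on its own tree (sum of separate marginal
#' likelihoods). \code{logBF = logML_B - logML_A}; positive values favour
#' separate phylogenies.
#'
#' @slot logMLA,logMLB scenario log marginal likelihoods.
#' @slot logMLa,logMLb the two separate-analysis components of B.
#' @slot sdA,sdB standard errors.
#' @slot logBF log Bayes factor, natural-log scale.
#' @slot interpretation Kass-Raftery category with favoured scenario.
#' @export
setClass("BayesFactorResult",
  representation(logMLA = "numeric", logMLB = "numeric", logMLa = "numeric",
    logMLb = "numeric", sdA = "numeric", sdB = "numeric", logBF = "numeric",
    interpretation = "character"))

#' Mantel test result
#'
#' @slot z raw cross-product statistic over unordered taxon pairs.
#' @slot r Pearson correlation over the same pairs.
#' @slot p one-tailed permutation p-value for positive association (on z).
#' @slot permutations number of permutations.
#' @slot seed integer seed.
#' @export
setClass("MantelResult",
  representation(z = "numeric", r = "numeric", p = "numeric",
    permutations = "integer", seed = "integer"))

#' Phylogenetic signal (Blomberg's K) over posterior trees
#'
#' @slot kMean mean K across the trees used.
#' @slot p tip-shuffle permutation p-value (same shuffles across trees).
#' @slot nTrees number of trees averaged over.
#' @slot permutations number of permutations.
#' @slot provenance description of the trait vector (e.g. "PC1").
#' @export
setClass("SignalResult",
  representation(kMean = "numeric", p = "numeric", nTrees = "integer",
    permutations = "integer", provenance = "character"))

setMethod("show", "TraitMatrix", function(object) {
  cat(sprintf("TraitMatrix: %d taxa x %d characters (%d missing entries)\n",
    nrow(object@states), ncol(object@states), sum(is.na(object@states))))
  if (!is.null(object@levels)) {
    tb <- table(object@levels)
    cat("  levels: ", paste(sprintf("L%s=%d", names(tb), tb), collapse = ", "),
      "\n", sep = "")
  }
  if (!is.null(object@categories)) {
    tb <- table(object@categories)
    cat("  categories: ",
      paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n", sep = "")
  }
  if (length(unique(object@weights)) > 1L)
    cat("  weights: ", paste(unique(object@weights), collapse = "/"),
      "\n", sep = "")
  invisible(object)
})

setMethod("show", "CovarionModel", function(object) {
  cat(sprintf(paste0("Binary covarion: pi=(%.3f, %.3f), alpha=%.3f, ",
    "switch=%.3f, rate=%.4g\n"), object@freq[1], object@freq[2],
    object@alpha, object@switchRate, object@overallRate))
  invisible(object)
})

setMethod("show", "PhyloPosterior", function(object) {
  cat(sprintf("PhyloPosterior: %d states (thin %d, burn-in %d, seed %d)\n",
    length(object@trees), object@sampleEvery, object@burnin, object@seed))
  invisible(object)
})

setMethod("show", "MantelResult", function(object) {
  cat(sprintf("Mantel test: z = %.4g, r = %.4f, p = %.4g (%d permutations)\n",
    object@z, object@r, object@p, object@permutations))
  invisible(object)
})

setMethod("show", "SignalResult", function(object) {
  cat(sprintf("Blomberg's K (%s): mean K = %.4f over %d trees, p = %.4g\n",
    object@provenance, object@kMean, object@nTrees, object@p))
  invisible(object)
})

setMethod("show", "BayesFactorResult", function(object) {
  cat(sprintf("log ML shared tree (A): %.2f (sd %.2f)\n", object@logMLA,
    object@sdA))
  cat(sprintf("log ML separate trees (B): %.2f (sd %.2f)\n", object@logMLB,
    object@sdB))
  cat(sprintf("log BF (B - A): %.2f -> %s\n", object@logBF,
    object@interpretation))
  invisible(object)
})

setMethod("show", "MarginalLikelihoodEstimate", function(object) {
  cat(sprintf("Stepping-stone log ML: %.3f (sd %.3f, %d steps)\n",
    object@logML, object@sd, length(object@betas)))
  invisible(object)
})
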