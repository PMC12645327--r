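## Likelihood of weighted, partitioned binary-covarion data on a time tree
## (Felsenstein pruning; compiled core in src/covarion_pruning.cpp).

# internal array encoding of a rooted time tree, with tips re-indexed to
# follow `tipOrder` (row order of the trait matrix)
ttreeFromPhylo <- function(phy, tipOrder = phy$tip.label) {
  n <- ape::Ntip(phy)
  if (!setequal(tipOrder, phy$tip.label) || length(tipOrder) != n)
    stop("matrix taxa and tree tips must coincide")
  perm <- integer(n + phy$Nnode)
  perm[match(tipOrder, phy$tip.label)] <- seq_len(n)   # old tip -> new tip
  perm[(n + 1L):(n + phy$Nnode)] <- (n + 1L):(n + phy$Nnode)
  parent <- integer(n + phy$Nnode)
  for (e in seq_len(nrow(phy$edge)))
    parent[perm[phy$edge[e, 2]]] <- perm[phy$edge[e, 1]]
  ages <- numeric(n + phy$Nnode)
  ages[perm] <- nodeAges(phy)
  list(parent = parent, ages = ages, nTip = n, labels = tipOrder,
    edgeChild = perm[phy$edge[, 2]])
}

# per-character class index and normalised multipliers from a partition
# scheme (character-weighted mean of multipliers forced to 1)
partitionClasses <- function(m, partition) {
  ids <- charIds(m)
  if (is.null(partition)) {
    return(list(classOfChar = rep(1L, length(ids)), classRate = 1))
  }
  validObject(partition)
  cls <- rep(NA_integer_, length(ids))
  for (g in seq_along(partition@groups))
    cls[ids %in% partition@groups[[g]]] <- g
  if (anyNA(cls))
    stop("characters not covered by partition: ",
      paste(head(ids[is.na(cls)], 5), collapse = ", "))
  r <- partition@rateMultipliers
  w <- charWeights(m)
  r <- r / (sum(w * r[cls]) / sum(w))
  list(classOfChar = cls, classRate = as.numeric(r))
}

# per-character (unweighted) log-likelihoods; workhorse behind the exported
# likelihood functions and the MCMC
perCharacterLogLik <- function(m, phy, model, clock = ClockModel(),
    partition = NULL, branchRates = NULL, eig = NULL) {
  tt <- ttreeFromPhylo(phy, taxa(m))
  pc <- partitionClasses(m, partition)
  if (is.null(eig)) eig <- covarionEigen(model)
  mult <- rep(1, length(tt$parent))
  if (!is.null(branchRates)) {
    if (length(branchRates) != nrow(phy$edge))
      stop("branchRates must have one entry per edge")
    mult[tt$edgeChild] <- branchRates / clock@meanRate
  }
  .covarionPruning(tt$parent, tt$ages, tt$nTip, mult, clock@meanRate,
    traitStates(m), pc$classOfChar, pc$classRate, eig$values, eig$V,
    eig$Vinv, eig$pi)
}

#' Log-likelihood of one character on a time tree
#'
#' Probability of the character's tip pattern under the binary covarion
#' model, summing the four hidden states at the root weighted by the
#' stationary distribution. Missing entries contribute all-ones tip partials.
#' Branch durations are multiplied by the clock rate and, when a partition is
#' given, by the character's (renormalised) partition multiplier.
#'
#' @param m a \linkS4class{TraitMatrix}.
#' @param phy an \code{ape::phylo} time tree with tips matching \code{taxa(m)}.
#' @param model a \linkS4class{CovarionModel}.
#' @param charIndex character index (or id).
#' @param clock a \linkS4class{ClockModel} (its mean rate scales all
#'   branches; for a relaxed clock pass realised \code{branchRates}).
#' @param partition optional \linkS4class{PartitionScheme}.
#' @param branchRates optional per-edge rates (ordered as \code{phy$edge}),
#'   e.g. from \code{drawBranchRates}.
#' @return log P(pattern | tree, model).
#' @export
characterLogLikelihood <- function(m, phy, model, charIndex,
    clock = ClockModel(), partition = NULL, branchRates = NULL) {
  if (is.character(charIndex)) charIndex <- match(charIndex, charIds(m))
  ll <- perCharacterLogLik(m, phy, model, clock, partition, branchRates)
  ll[charIndex]
}

#' Total weighted log-likelihood of a trait matrix on a time tree
#'
#' Sum over characters of weight x per-character log-likelihood. An integer
#' weight w is exactly equivalent to replicating the character w times.
#'
#' @inheritParams characterLogLikelihood
#' @param weights optional override of the matrix's per-character weights
#'   (non-negative; a zero drops the character, which is how subsetting and
#'   weighting are reconciled).
#' @return Total log-likelihood.
#' @examples
#' m <- TraitMatrix(rbind(A = c(1, 0), B = c(0, 1)))
#' tr <- parseTimeTree("(A:1,B:1);")
#' totalLogLikelihood(m, tr, CovarionModel())
#' @export
totalLogLikelihood <- function(m, phy, model, clock = ClockModel(),
    partition = NULL, branchRates = NULL, weights = NULL) {
  ll <- perCharacterLogLik(m, phy, model, clock, partition, branchRates)
  w <- if (is.null(weights)) charWeights(m) else weights
  if (length(w) != length(ll)) stop("one weight per character required")
  sum(w * ll)
}
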