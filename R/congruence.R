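## Cross-phylogeny congruence statistics: averaged patristic distance
## matrices, Mantel tests, PCA projection of binary tip data, and Blomberg's
## K averaged over posterior trees.

#' Posterior-averaged patristic distance matrix
#'
#' Subsamples \code{n} trees without replacement, optionally normalises each
#' by its depth (so deeper trees get no undue weight), prunes to the taxa of
#' interest and averages the patristic matrices element-wise.
#'
#' @param trees a \linkS4class{PhyloPosterior} or list of \code{ape::phylo}.
#' @param taxaOrder taxon labels fixing row/column order.
#' @param n number of trees to use (default all).
#' @param normalise depth-normalise each tree first (default TRUE).
#' @param seed integer seed for the subsample.
#' @return Symmetric matrix over \code{taxaOrder}.
#' @export
posteriorMeanDistances <- function(trees, taxaOrder, n = NULL,
    normalise = TRUE, seed = 1) {
  if (is(trees, "PhyloPosterior")) trees <- trees@trees
  if (is.null(n)) n <- length(trees)
  if (n > length(trees)) stop("n exceeds the number of available trees")
  set.seed(as.integer(seed))
  pick <- if (n == length(trees)) seq_len(n) else sample(length(trees), n)
  acc <- matrix(0, length(taxaOrder), length(taxaOrder),
    dimnames = list(taxaOrder, taxaOrder))
  for (i in pick) {
    tr <- trees[[i]]
    if (normalise) tr <- normaliseByDepth(tr)
    if (length(tr$tip.label) > length(taxaOrder))
      tr <- pruneTips(tr, taxaOrder)
    acc <- acc + patristicMatrix(tr, taxaOrder)
  }
  acc / length(pick)
}

#' Mantel test between two distance matrices
#'
#' Statistic \code{z = sum_(i<j) Da[i,j] * Db[i,j]} (with the Pearson
#' correlation r over the same pairs reported alongside); the null permutes
#' rows and columns of Db simultaneously, and the one-tailed p-value for
#' positive association is \code{(1 + #\{z_perm >= z\}) / (1 + permutations)}.
#'
#' @param Da,Db symmetric matrices with matching dimensions (>= 4 taxa).
#' @param permutations number of permutations (>= 99; 999 gives the
#'   conventional p-floor of 0.001).
#' @param seed integer seed.
#' @return A \linkS4class{MantelResult}.
#' @export
mantelTest <- function(Da, Db, permutations = 999, seed = 1) {
  Da <- as.matrix(Da); Db <- as.matrix(Db)
  if (!all(dim(Da) == dim(Db))) stop("dimension mismatch")
  nn <- nrow(Da)
  if (nn < 4) stop("need at least 4 taxa")
  if (permutations < 99) stop("need at least 99 permutations")
  ut <- upper.tri(Da)
  va <- Da[ut]
  z <- sum(va * Db[ut])
  r <- if (sd(va) == 0 || sd(Db[ut]) == 0) {
    warning("constant distance matrix: r undefined (z still reported)")
    NA_real_
  } else cor(va, Db[ut])
  set.seed(as.integer(seed))
  zperm <- vapply(seq_len(permutations), function(k) {
    pp <- sample.int(nn)
    sum(va * Db[pp, pp][ut])
  }, 0)
  p <- (1 + sum(zperm >= z - 1e-12)) / (1 + permutations)
  new("MantelResult", z = z, r = r, p = p,
    permutations = as.integer(permutations), seed = as.integer(seed))
}

#' First principal component of binary tip data
#'
#' Missing entries are imputed by the character mean, columns are mean
#' centred, and per-taxon scores along the first right singular direction
#' are returned. The sign convention makes the largest-magnitude score
#' positive (ties broken by taxon label), which is deterministic and
#' invariant under character reordering.
#'
#' @param m a \linkS4class{TraitMatrix} with >= 2 taxa and >= 2 characters.
#' @return Named per-taxon scores.
#' @export
firstPrincipalComponent <- function(m) {
  X <- traitStates(m)
  if (nrow(X) < 2 || ncol(X) < 2) stop("need >= 2 taxa and >= 2 characters")
  X <- apply(X, 2, function(col) {
    mu <- mean(col, na.rm = TRUE)
    col[is.na(col)] <- mu
    col
  })
  X <- sweep(X, 2, colMeans(X))
  if (all(abs(X) < 1e-12)) stop("zero-variance matrix: no principal axis")
  sv <- svd(X)
  v1 <- sv$v[, 1]
  scores <- as.numeric(X %*% v1)
  # sign anchored on the scores (taxa are never permuted): the largest-
  # magnitude score is made positive, ties broken by taxon label, so the
  # orientation is invariant under character permutation even with tied
  # loadings
  cand <- which(abs(scores) >= max(abs(scores)) - 1e-8)
  pick <- cand[order(taxa(m)[cand])[1]]
  sgn <- sign(scores[pick])
  if (sgn == 0) sgn <- 1
  scores <- scores * sgn
  names(scores) <- taxa(m)
  scores
}

# per-tree quantities reused across permutations
kTreeCache <- function(phy, tipOrder) {
  C <- ape::vcv.phylo(phy)[tipOrder, tipOrder]
  Cinv <- tryCatch(solve(C), error = function(e)
    stop("singular tip covariance (condition number ",
      signif(kappa(C), 3), ")"))
  nn <- nrow(C)
  expectedRatio <- (sum(diag(C)) - nn / sum(Cinv)) / (nn - 1)
  list(Cinv = Cinv, ones = rep(1, nn), expectedRatio = expectedRatio,
    n = nn)
}

kFromCache <- function(cache, x) {
  a <- sum(cache$Cinv %*% x) / sum(cache$Cinv)
  d <- x - a
  mse0 <- sum(d^2) / (cache$n - 1)
  mse <- as.numeric(d %*% cache$Cinv %*% d) / (cache$n - 1)
  (mse0 / mse) / cache$expectedRatio
}

#' Blomberg's K on one tree
#'
#' Ratio of the observed MSE0/MSE (MSE0 around the phylogenetic GLS mean,
#' MSE under the tree's tip variance-covariance) to its expectation under
#' Brownian motion on the tree. K near 1 matches Brownian expectation;
#' K > 1 indicates stronger-than-Brownian phylogenetic signal. Computed
#' directly from the tip covariance, so non-ultrametric (e.g. consensus)
#' trees are handled without modification.
#'
#' @param phy an \code{ape::phylo} tree with >= 4 tips and positive depth.
#' @param x named per-taxon values covering the tree's tips.
#' @return K >= 0.
#' @export
blombergK <- function(phy, x) {
  if (ape::Ntip(phy) < 4) stop("need at least 4 tips")
  if (is.null(names(x))) stop("x must be named by tip label")
  missing <- setdiff(phy$tip.label, names(x))
  if (length(missing) > 0)
    stop("x missing tips: ", paste(missing, collapse = ", "))
  if (sd(x) == 0) stop("constant trait vector: K undefined")
  cache <- kTreeCache(phy, phy$tip.label)
  kFromCache(cache, x[phy$tip.label])
}

#' Blomberg's K averaged over posterior trees, with a permutation test
#'
#' Maps the trait vector onto every tree, averages K, and obtains a p-value
#' by shuffling tip labels (the same shuffles across all trees):
#' \code{p = (1 + #\{mean K_perm >= mean K\}) / (1 + permutations)}, so 999
#' permutations give a p-floor of 0.001.
#'
#' @param trees a \linkS4class{PhyloPosterior} or list of trees sharing the
#'   tips named in \code{x}.
#' @param x named per-taxon values.
#' @param permutations number of tip shuffles.
#' @param seed integer seed.
#' @param provenance label recorded in the result (e.g. "PC1 of looms").
#' @return A \linkS4class{SignalResult}.
#' @export
kOverPosterior <- function(trees, x, permutations = 999, seed = 1,
    provenance = "PC1") {
  if (is(trees, "PhyloPosterior")) trees <- trees@trees
  if (length(trees) == 0) stop("no trees supplied")
  tipOrder <- names(x)
  trees <- lapply(trees, function(tr)
    if (length(tr$tip.label) > length(tipOrder)) pruneTips(tr, tipOrder)
    else tr)
  caches <- lapply(trees, kTreeCache, tipOrder = tipOrder)
  xo <- x[tipOrder]
  kMean <- mean(vapply(caches, kFromCache, 0, x = xo))
  set.seed(as.integer(seed))
  kperm <- vapply(seq_len(permutations), function(b) {
    xp <- xo[sample.int(length(xo))]
    mean(vapply(caches, kFromCache, 0, x = xp))
  }, 0)
  p <- (1 + sum(kperm >= kMean - 1e-12)) / (1 + permutations)
  new("SignalResult", kMean = kMean, p = p, nTrees = length(trees),
    permutations = as.integer(permutations), provenance = provenance)
}
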