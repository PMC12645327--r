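## Rooted time trees are ape::phylo objects with branch lengths in time units.
## Node ages (years BP or any consistent unit) are derived: the deepest
## root-to-tip path defines the present, so contemporaneous tips get age 0 and
## shorter tip paths (fossils) get positive ages.

#' Parse a newick string into a rooted time tree
#'
#' @param text newick string with branch lengths.
#' @return An \code{ape::phylo} tree.
#' @examples
#' tr <- parseTimeTree("(A:2,(B:1,C:1):1);")
#' nodeAges(tr)
#' @export
parseTimeTree <- function(text) {
  tr <- tryCatch(suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("newick parse error in: ", substr(text, 1, 60))
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
      paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length) || anyNA(tr$edge.length))
    stop("newick tree must have branch lengths on every edge")
  if (any(tr$edge.length < 0)) stop("negative branch length")
  tr
}

#' Node ages of a time tree
#'
#' Ages are measured backwards from the present, defined by the deepest
#' root-to-tip path: \code{age = max depth - node depth}.
#'
#' @param phy an \code{ape::phylo} tree with branch lengths.
#' @return Numeric vector over node indices (tips first, then internal
#'   nodes, ape numbering).
#' @export
nodeAges <- function(phy) {
  n <- ape::Ntip(phy)
  nn <- n + phy$Nnode
  depth <- numeric(nn)
  root <- n + 1L
  eo <- order(phy$edge[, 1])  # parents in increasing index: preorder-safe
  # preorder traversal: process edges so parent depth is known first
  ord <- preorderEdges(phy)
  for (e in ord)
    depth[phy$edge[e, 2]] <- depth[phy$edge[e, 1]] + phy$edge.length[e]
  ages <- max(depth[seq_len(n)]) - depth
  ages[abs(ages) < 1e-12] <- 0
  ages
}

# edge indices ordered so that each parent is visited before its children
preorderEdges <- function(phy) {
  n <- ape::Ntip(phy)
  root <- n + 1L
  children <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
  ord <- integer(0)
  stack <- as.character(root)
  while (length(stack) > 0) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    es <- children[[nd]]
    if (!is.null(es)) {
      ord <- c(ord, es)
      stack <- c(stack, as.character(phy$edge[es, 2]))
    }
  }
  ord
}

#' Tree depth (maximum root-to-tip path length)
#' @param phy an \code{ape::phylo} tree.
#' @export
treeDepth <- function(phy) {
  ages <- nodeAges(phy)
  ages[ape::Ntip(phy) + 1L]
}

#' Patristic distance matrix
#'
#' Entry (i, j) is the sum of branch lengths on the path between tips i and j
#' through their most recent common ancestor.
#'
#' @param phy an \code{ape::phylo} tree.
#' @param order optional taxon labels selecting/ordering rows and columns.
#' @return Symmetric matrix with zero diagonal.
#' @export
patristicMatrix <- function(phy, order = NULL) {
  d <- as.matrix(ape::cophenetic.phylo(phy))
  if (is.null(order)) order <- sort(phy$tip.label)
  unknown <- setdiff(order, phy$tip.label)
  if (length(unknown) > 0)
    stop("unknown tip label: ", paste(unknown, collapse = ", "))
  d[order, order, drop = FALSE]
}

#' Normalise a tree by its depth
#'
#' Divides every branch length by the maximum root-to-tip path length, so the
#' rescaled tree has depth exactly 1. Used to stop deeper posterior trees
#' dominating averaged distance matrices.
#'
#' @param phy an \code{ape::phylo} tree.
#' @return The rescaled tree.
#' @export
normaliseByDepth <- function(phy) {
  d <- treeDepth(phy)
  if (d <= 0) stop("degenerate tree: depth is zero")
  phy$edge.length <- phy$edge.length / d
  phy
}

#' Prune a tree to a set of tips
#'
#' Returns the induced tree on \code{keep}: unsampled tips are removed and
#' degree-2 nodes suppressed with branch lengths summed, so pairwise
#' patristic distances among kept tips are preserved exactly.
#'
#' @param phy an \code{ape::phylo} tree.
#' @param keep tip labels to retain (at least 2).
#' @export
pruneTips <- function(phy, keep) {
  unknown <- setdiff(keep, phy$tip.label)
  if (length(unknown) > 0)
    stop("unknown tip label: ", paste(unknown, collapse = ", "))
  if (length(keep) < 2) stop("at least two tips must be kept")
  ape::keep.tip(phy, keep)
}

#' Age of the most recent common ancestor of a set of tips
#'
#' @param phy an \code{ape::phylo} tree.
#' @param tips non-empty set of tip labels; a singleton returns the tip's own
#'   age.
#' @return Age in the tree's time units.
#' @export
mrcaAge <- function(phy, tips) {
  unknown <- setdiff(tips, phy$tip.label)
  if (length(unknown) > 0)
    stop("unknown tip label: ", paste(unknown, collapse = ", "))
  if (length(tips) == 0) stop("tips must be non-empty")
  ages <- nodeAges(phy)
  if (length(tips) == 1) return(ages[match(tips, phy$tip.label)])
  ages[ape::getMRCA(phy, tips)]
}

# clade tip-sets (as sorted indices into `ref` label order) and their node
# ages, for every internal node of phy
cladeTable <- function(phy, ref) {
  n <- ape::Ntip(phy)
  ages <- nodeAges(phy)
  po <- rev(preorderEdges(phy))
  sets <- vector("list", n + phy$Nnode)
  for (i in seq_len(n)) sets[[i]] <- match(phy$tip.label[i], ref)
  for (e in po) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  idx <- (n + 1L):(n + phy$Nnode)
  keys <- vapply(sets[idx], function(s) paste(sort(s), collapse = ","), "")
  list(keys = keys, ages = ages[idx], sets = lapply(sets[idx], sort),
    tipAges = ages[seq_len(n)][match(ref, phy$tip.label)])
}

#' Majority-rule consensus tree with clade supports and mean node ages
#'
#' Contains exactly the clades whose frequency in the sample is at least
#' \code{threshold} (inclusive, so "50\% or more" at the default). Each
#' retained clade is annotated with its frequency in per cent
#' (\code{node.label}); its age is the mean MRCA age over the trees that
#' contain it, which generally yields a non-ultrametric tree. Among mutually
#' incompatible clades at identical frequency (possible only at exactly the
#' threshold for threshold = 0.5) the lexicographically smallest tip set is
#' kept, for determinism.
#'
#' @param trees list of \code{ape::phylo} trees over one tip set.
#' @param threshold clade frequency cutoff in (0, 1], default 0.5.
#' @return An \code{ape::phylo} tree with numeric percentage supports in
#'   \code{node.label} and a \code{"supports"} attribute.
#' @export
majorityConsensus <- function(trees, threshold = 0.5) {
  if (length(trees) == 0) stop("empty tree collection")
  if (inherits(trees, "phylo")) trees <- list(trees)
  # extract with [[ dispatch so compressed multiPhylo tip labels survive
  trees <- lapply(seq_along(trees), function(i) trees[[i]])
  ref <- sort(trees[[1]]$tip.label)
  for (tr in trees)
    if (!identical(sort(tr$tip.label), ref))
      stop("all trees must share the same tip set")
  n <- length(ref)
  tabs <- lapply(trees, cladeTable, ref = ref)
  keys <- unlist(lapply(tabs, `[[`, "keys"))
  ages <- unlist(lapply(tabs, `[[`, "ages"))
  cnt <- table(keys)
  meanAge <- tapply(ages, keys, mean)
  freq <- as.numeric(cnt) / length(trees)
  names(freq) <- names(cnt)
  keep <- names(freq)[freq >= threshold - 1e-12]
  sets <- lapply(strsplit(keep, ","), as.integer)
  lexKey <- vapply(sets, function(s)
    paste(ref[s], collapse = "\r"), "")
  ordks <- order(-freq[keep], lexKey)
  accepted <- list(); accKeys <- character()
  compatible <- function(a, b) {
    i <- length(intersect(a, b))
    i == 0 || i == length(a) || i == length(b)
  }
  for (k in ordks) {
    s <- sets[[k]]
    if (all(vapply(accepted, compatible, TRUE, b = s))) {
      accepted <- c(accepted, list(s))
      accKeys <- c(accKeys, keep[k])
    }
  }
  rootKey <- paste(seq_len(n), collapse = ",")
  if (!rootKey %in% accKeys) {  # root clade always present in rooted trees
    accepted <- c(accepted, list(seq_len(n)))
    accKeys <- c(accKeys, rootKey)
  }
  sz <- vapply(accepted, length, 0L)
  ordsz <- order(-sz)
  accepted <- accepted[ordsz]; accKeys <- accKeys[ordsz]
  m <- length(accepted)
  # parent of clade j = smallest accepted clade strictly containing it
  parentClade <- integer(m)
  for (j in seq_len(m)[-1]) {
    cand <- which(vapply(seq_len(m), function(i)
      i != j && length(accepted[[i]]) > length(accepted[[j]]) &&
        all(accepted[[j]] %in% accepted[[i]]), TRUE))
    parentClade[j] <- cand[which.min(sz[ordsz][cand])]
  }
  tipParent <- vapply(seq_len(n), function(i) {
    cand <- which(vapply(accepted, function(s) i %in% s, TRUE))
    cand[which.min(vapply(accepted[cand], length, 0L))]
  }, 0L)
  tipAgeMat <- vapply(tabs, `[[`, numeric(n), "tipAges")
  tipAge <- if (n == 1) mean(tipAgeMat) else rowMeans(matrix(tipAgeMat, n))
  cladeAge <- as.numeric(meanAge[accKeys])
  # enforce parent age >= child age (means over different subsets can invert)
  for (j in rev(seq_len(m)[-1]))
    cladeAge[parentClade[j]] <- max(cladeAge[parentClade[j]], cladeAge[j])
  for (i in seq_len(n))
    cladeAge[tipParent[i]] <- max(cladeAge[tipParent[i]], tipAge[i])
  for (j in seq_len(m)[-1])  # re-propagate upward after tip clamping
    for (jj in rev(seq_len(m)[-1]))
      cladeAge[parentClade[jj]] <- max(cladeAge[parentClade[jj]],
        cladeAge[jj])
  edge <- rbind(
    cbind(n + parentClade[-1], n + seq_len(m)[-1]),
    cbind(n + tipParent, seq_len(n)))
  edgeLen <- c(cladeAge[parentClade[-1]] - cladeAge[-1],
    cladeAge[tipParent] - tipAge)
  supports <- round(100 * as.numeric(freq[accKeys]), 6)
  supports[accKeys == rootKey] <- max(supports[accKeys == rootKey], 100)
  phy <- structure(list(edge = edge, edge.length = pmax(edgeLen, 0),
    tip.label = ref, Nnode = m,
    node.label = as.character(supports)), class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  attr(phy, "supports") <- supports
  phy
}

#' Clade recovery fraction between a reference tree and a consensus
#'
#' Fraction of the reference tree's non-root clades that appear in
#' \code{consensusTree} (which, from \code{majorityConsensus}, means they
#' reached the support threshold).
#'
#' @param trueTree,consensusTree \code{ape::phylo} trees over the same tips.
#' @export
cladeRecovery <- function(trueTree, consensusTree) {
  ref <- sort(trueTree$tip.label)
  kTrue <- cladeTable(trueTree, ref)$keys
  kCons <- cladeTable(consensusTree, ref)$keys
  rootKey <- paste(seq_along(ref), collapse = ",")
  kTrue <- setdiff(kTrue, rootKey)
  if (length(kTrue) == 0) return(1)
  mean(kTrue %in% kCons)
}
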