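# Shared fixtures and independent oracles for the test suite.

# exhaustive hidden-state enumeration of the covarion likelihood: sums over
# every assignment of the 4 covarion states to the internal nodes, with tip
# contributions folded in through explicit transition-probability products.
# Independent of the pruning code path.
enumLogLik <- function(m, phy, model, char) {
  Q <- covarionGenerator(model)
  pi4 <- covarionStationary(model)
  n <- ape::Ntip(phy)
  Ps <- lapply(seq_len(nrow(phy$edge)), function(e)
    transitionProbabilities(Q, phy$edge.length[e]))
  tipPart <- function(st)
    if (is.na(st)) rep(1, 4) else if (st == 0) c(1, 0, 1, 0) else c(0, 1, 0, 1)
  states <- traitStates(m)[phy$tip.label, char]
  grid <- as.matrix(expand.grid(rep(list(1:4), phy$Nnode)))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    assign <- grid[g, ]
    pr <- pi4[assign[1]]   # root is internal node n + 1
    for (e in seq_len(nrow(phy$edge))) {
      pa <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
      spar <- assign[pa - n]
      pr <- pr * if (ch <= n) sum(Ps[[e]][spar, ] * tipPart(states[ch])) else
        Ps[[e]][spar, assign[ch - n]]
    }
    tot <- tot + pr
  }
  log(tot)
}

# random binary matrix over the tips of a tree
randomMatrix <- function(phy, nChar, pMissing = 0, seed = 1) {
  set.seed(seed)
  n <- ape::Ntip(phy)
  st <- matrix(sample(c(0L, 1L), n * nChar, TRUE), n, nChar,
    dimnames = list(phy$tip.label, paste0("c", seq_len(nChar))))
  if (pMissing > 0)
    st[sample(length(st), round(pMissing * length(st)))] <- NA
  TraitMatrix(st)
}

# level partition scheme over an annotated matrix
levelScheme <- function(m) {
  gr <- split(charIds(m), charLevels(m))
  new("PartitionScheme", name = "levels", groups = gr,
    rateMultipliers = setNames(rep(1, length(gr)), names(gr)))
}

# fixture mirroring the study's loom annotation structure: 216 characters,
# categories 159 structure / 27 simple / 30 complex patterning, levels with
# 102 L2 and 13 L4 characters
loomLikeFixture <- function(nTaxa = 6, seed = 42) {
  set.seed(seed)
  categories <- rep(c("structure", "simple-patterning", "complex-patterning"),
    c(159, 27, 30))
  levels <- rep(c(1L, 2L, 3L, 4L), c(99L, 102L, 2L, 13L))
  st <- matrix(sample(c(0L, 1L), nTaxa * 216, TRUE), nTaxa, 216,
    dimnames = list(paste0("loom", seq_len(nTaxa)), paste0("c", 1:216)))
  TraitMatrix(st, levels = levels, categories = categories)
}
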