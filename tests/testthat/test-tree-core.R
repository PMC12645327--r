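test_that("newick parsing reconstructs ages and flags malformed input", {
  tr <- parseTimeTree("(A:1,B:1);")
  ages <- nodeAges(tr)
  expect_equal(unname(ages[1:2]), c(0, 0))
  expect_equal(treeDepth(tr), 1)
  tr2 <- parseTimeTree("(A:2,(B:1,C:1):1);")
  expect_equal(treeDepth(tr2), 2)
  expect_equal(unname(nodeAges(tr2)[ape::getMRCA(tr2, c("B", "C"))]), 1)
  expect_error(parseTimeTree("((A:1,B:1;"), "parse")
  expect_error(parseTimeTree("(A:1,A:1);"), "duplicate")
})

test_that("patristic distances are path sums, symmetric, zero-diagonal", {
  tr <- parseTimeTree("(A:1,B:1);")
  expect_equal(patristicMatrix(tr)["A", "B"], 2)
  tr2 <- parseTimeTree("(A:2,(B:1,C:1):1);")
  d <- patristicMatrix(tr2, c("A", "B", "C"))
  expect_equal(d["B", "C"], 2)   # hand path sum: 1 + 1
  expect_equal(d["A", "B"], 4)   # 2 + 1 + 1
  expect_equal(diag(d), c(A = 0, B = 0, C = 0))
  expect_equal(d, t(d))
  expect_error(patristicMatrix(tr2, c("A", "Z")), "Z")

  # four-point condition on random trees
  for (s in 1:5) {
    phy <- simulateTimeTree(6, BirthDeathParams(1.5, 0.2, 1), 3, seed = s)
    dd <- patristicMatrix(phy)
    cmb <- utils::combn(6, 4)
    for (k in seq_len(ncol(cmb))) {
      q <- cmb[, k]
      s1 <- dd[q[1], q[2]] + dd[q[3], q[4]]
      s2 <- dd[q[1], q[3]] + dd[q[2], q[4]]
      s3 <- dd[q[1], q[4]] + dd[q[2], q[3]]
      two <- sort(c(s1, s2, s3), decreasing = TRUE)[1:2]
      expect_lt(abs(two[1] - two[2]), 1e-8)
    }
  }
})

test_that("depth normalisation scales to unit depth and commutes with distances", {
  tr <- parseTimeTree("(A:5,(B:2,C:2):3);")
  nt <- normaliseByDepth(tr)
  expect_equal(treeDepth(nt), 1)
  expect_equal(patristicMatrix(nt), patristicMatrix(tr) / 5)
  expect_equal(normaliseByDepth(nt)$edge.length, nt$edge.length)
  zero <- parseTimeTree("(A:1,B:1);")
  zero$edge.length <- c(0, 0)
  expect_error(normaliseByDepth(zero), "degenerate")
})

test_that("pruning preserves patristic distances and rejects degenerate keeps", {
  tr <- parseTimeTree("(A:2,(B:1,C:1):1);")
  pr <- pruneTips(tr, c("A", "B"))
  expect_equal(patristicMatrix(pr, c("A", "B"))["A", "B"], 4)
  expect_identical(sort(pruneTips(tr, c("A", "B", "C"))$tip.label),
    sort(tr$tip.label))
  expect_error(pruneTips(tr, "A"), "two tips")
  expect_error(pruneTips(tr, c("A", "Z")), "Z")
  for (s in 1:5) {
    phy <- simulateTimeTree(8, BirthDeathParams(1.5, 0.2, 1), 3, seed = s)
    keep <- sample(phy$tip.label, 4)
    expect_equal(patristicMatrix(pruneTips(phy, keep), sort(keep)),
      patristicMatrix(phy, sort(keep)), tolerance = 1e-10)
  }
})

test_that("MRCA ages cover root, internal and singleton cases", {
  tr <- parseTimeTree("(A:2,(B:1,C:1):1);")
  expect_equal(mrcaAge(tr, c("A", "B", "C")), 2)
  expect_equal(mrcaAge(tr, c("B", "C")), 1)
  expect_equal(unname(mrcaAge(tr, "B")), 0)
  expect_error(mrcaAge(tr, c("B", "Z")), "Z")
})

test_that("majority consensus matches exhaustive clade counting", {
  t1 <- parseTimeTree("((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
  t2 <- parseTimeTree("((A:1,B:1):0.6,(C:1.2,D:1.2):0.4);")
  t3 <- parseTimeTree("(((A:1,B:1):0.5,D:1.5):0.5,C:2);")
  t4 <- parseTimeTree("(((A:1,C:1):0.5,D:1.5):0.5,B:2);")
  # clade frequencies: AB 3/4, CD 2/4, AC 1/4
  cons <- majorityConsensus(list(t1, t2, t3, t4))
  key <- function(tips, tr) all(tips %in%
    ape::extract.clade(tr, ape::getMRCA(tr, tips))$tip.label) &&
    length(ape::extract.clade(tr, ape::getMRCA(tr, tips))$tip.label) ==
      length(tips)
  expect_true(key(c("A", "B"), cons))
  expect_true(key(c("C", "D"), cons))   # at exactly 50%: inclusive
  expect_false(key(c("A", "C"), cons))
  sup <- attr(cons, "supports")
  expect_setequal(sup, c(100, 75, 50))

  # unanimity: identical trees give identical topology at support 100
  cons2 <- majorityConsensus(list(t1, t1, t1))
  expect_true(all(attr(cons2, "supports") == 100))
  expect_equal(sort(patristicMatrix(cons2)), sort(patristicMatrix(t1)),
    tolerance = 1e-10)

  # consensus node ages are means over the trees containing each clade
  abAge <- mean(c(1, 0.6 + 1 - 0.6, 1)) # MRCA(A,B) ages in t1, t2, t3
  abAge <- mean(c(mrcaAge(t1, c("A", "B")), mrcaAge(t2, c("A", "B")),
    mrcaAge(t3, c("A", "B"))))
  expect_equal(mrcaAge(cons, c("A", "B")), abAge, tolerance = 1e-10)

  expect_error(majorityConsensus(list(t1,
    parseTimeTree("(A:1,(B:1,X:1):1);"))), "tip set")

  # threshold 0.5 consensus never contains incompatible bipartitions
  set.seed(3)
  for (rep in 1:3) {
    trees <- lapply(1:7, function(i)
      simulateTimeTree(6, BirthDeathParams(2, 0, 1), 3, seed = rep * 10 + i))
    trees <- lapply(trees, function(tr) {
      tr$tip.label <- paste0("t", 1:6); tr })
    cons <- majorityConsensus(trees)
    # a valid phylo object with all tips implies pairwise-compatible clades
    expect_s3_class(cons, "phylo")
    expect_identical(sort(cons$tip.label), paste0("t", 1:6))
    expect_true(all(attr(cons, "supports") >= 50 - 1e-9))
  }
})
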