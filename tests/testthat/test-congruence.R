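test_that("posterior-mean distances: identity, normalisation, arithmetic oracle", {
  t1 <- parseTimeTree("((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
  ord <- c("A", "B", "C", "D")
  # identical trees average to the single-tree matrix
  expect_equal(posteriorMeanDistances(rep(list(t1), 5), ord,
    normalise = FALSE), patristicMatrix(t1, ord))
  # depth normalisation collapses pure rescalings
  t2 <- t1; t2$edge.length <- t1$edge.length * 7
  got <- posteriorMeanDistances(list(t1, t2), ord, normalise = TRUE)
  expect_equal(got, patristicMatrix(normaliseByDepth(t1), ord),
    tolerance = 1e-12)
  # element-wise mean against per-tree hand sums (3 trees)
  t3 <- parseTimeTree("(((A:1,B:1):0.5,C:1.5):0.5,D:2);")
  avg <- posteriorMeanDistances(list(t1, t2, t3), ord, normalise = FALSE)
  hand <- (patristicMatrix(t1, ord) + patristicMatrix(t2, ord) +
    patristicMatrix(t3, ord)) / 3
  expect_equal(avg, hand, tolerance = 1e-12)
  expect_error(posteriorMeanDistances(list(t1), ord, n = 5), "exceeds")
})

test_that("Mantel test: self-congruence, exhaustive null, permutation scheme", {
  phy <- simulateTimeTree(8, BirthDeathParams(1.5, 0.25, 1), 3, seed = 3)
  D <- patristicMatrix(phy)
  self <- mantelTest(D, D, permutations = 999, seed = 1)
  expect_identical(self@r, 1)
  expect_identical(self@p, 1 / 1000)
  # z is the raw cross-product over unordered pairs
  expect_equal(self@z, sum(D[upper.tri(D)]^2))
  # exhaustive null at 4 taxa: all 4! relabelings enumerated
  D1 <- matrix(c(0, 1, 4, 5, 1, 0, 3, 6, 4, 3, 0, 2, 5, 6, 2, 0), 4, 4)
  D2 <- matrix(c(0, 2, 5, 4, 2, 0, 4, 5, 5, 4, 0, 1, 4, 5, 1, 0), 4, 4)
  ut <- upper.tri(D1)
  zobs <- sum(D1[ut] * D2[ut])
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  zAll <- apply(perms, 1, function(p) sum(D1[ut] * D2[p, p][ut]))
  pExact <- mean(zAll >= zobs - 1e-12)
  mt <- mantelTest(D1, D2, permutations = 9999, seed = 4)
  expect_lt(abs(mt@p - pExact), 0.02)
  expect_error(mantelTest(D[1:3, 1:3], D[1:3, 1:3]), "4 taxa")
  expect_error(mantelTest(D, D[1:7, 1:7]), "mismatch")
  expect_warning(mantelTest(matrix(1, 5, 5) - diag(5), D[1:5, 1:5],
    permutations = 99), "constant")
})

test_that("Mantel agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(6)
  D1 <- as.matrix(dist(matrix(rnorm(60), 12)))
  D2 <- as.matrix(dist(matrix(rnorm(60), 12)))
  mt <- mantelTest(D1, D2, permutations = 999, seed = 7)
  vg <- vegan::mantel(stats::as.dist(D1), stats::as.dist(D2),
    permutations = 999)
  expect_equal(mt@r, unname(vg$statistic), tolerance = 1e-10)
  expect_lt(abs(mt@p - vg$signif), 0.06)
})

test_that("PCA scores separate blocks and match the eigendecomposition", {
  st <- rbind(A = c(1L, 1L, 0L), B = c(1L, 1L, 0L), C = c(0L, 0L, 1L),
    D = c(0L, 0L, 1L))
  m <- TraitMatrix(st)
  sc <- firstPrincipalComponent(m)
  expect_identical(length(unique(round(sc, 10))), 2L)
  expect_true(all(sc[c("A", "B")] != sc[c("C", "D")]))
  # invariance under character permutation (sign-fixed)
  m2 <- TraitMatrix(st[, c(3, 1, 2)])
  expect_equal(firstPrincipalComponent(m2), sc, tolerance = 1e-12)
  # eigen oracle on a hand matrix with a missing entry (mean-imputed)
  st4 <- rbind(A = c(1L, 0L, 1L), B = c(0L, 1L, NA), C = c(1L, 1L, 0L),
    D = c(0L, 0L, 1L))
  m4 <- TraitMatrix(st4)
  X <- apply(st4, 2, function(col) {
    col[is.na(col)] <- mean(col, na.rm = TRUE); col })
  X <- sweep(X, 2, colMeans(X))
  ev <- eigen(crossprod(X))
  s0 <- as.numeric(X %*% ev$vectors[, 1])
  s0 <- s0 * sign(s0[which.max(abs(s0))])  # same orientation convention
  expect_equal(unname(firstPrincipalComponent(m4)), s0, tolerance = 1e-10)
  expect_error(firstPrincipalComponent(TraitMatrix(matrix(1L, 3, 3,
    dimnames = list(letters[1:3], letters[4:6])))), "zero-variance")
})

test_that("Blomberg's K: affine invariance, star-tree case, signal destruction", {
  phy <- simulateTimeTree(16, BirthDeathParams(1.5, 0.25, 1), 3, seed = 7)
  x <- setNames(ape::rTraitCont(phy, model = "BM"), phy$tip.label)
  k <- blombergK(phy, x)
  expect_gte(k, 0)
  expect_equal(blombergK(phy, 5 * x - 2), k, tolerance = 1e-10)
  expect_error(blombergK(phy, setNames(rep(1, 16), phy$tip.label)),
    "constant")
  expect_error(blombergK(parseTimeTree("(A:1,(B:1,C:1):1);"),
    c(A = 1, B = 2, C = 3)), "4 tips")
  # star tree: C = depth x I, expected MSE0/MSE ratio is analytic
  star <- structure(list(edge = cbind(rep(9L, 8), 1:8),
    edge.length = rep(2, 8), tip.label = paste0("t", 1:8), Nnode = 1L),
    class = "phylo")
  cacheRatio <- (8 * 2 - 8 / (8 / 2)) / 7   # (tr(C) - n/sum(Cinv))/(n-1)
  set.seed(8)
  ks <- replicate(400, blombergK(star,
    setNames(rnorm(8), paste0("t", 1:8))))
  expect_lt(abs(mean(ks) - 1), 0.1)  # iid x on a star tree: K ~= 1
  # permuting BM-generated tips destroys signal
  set.seed(9)
  worse <- replicate(40, {
    xb <- setNames(ape::rTraitCont(phy, model = "BM"), phy$tip.label)
    kb <- blombergK(phy, xb)
    xp <- setNames(sample(xb), names(xb))
    blombergK(phy, xp) < kb
  })
  expect_gte(mean(worse), 0.9)
})

test_that("K matches an independent implementation", {
  skip_if_not_installed("picante")
  phy <- simulateTimeTree(12, BirthDeathParams(1.5, 0.25, 1), 3, seed = 10)
  x <- setNames(ape::rTraitCont(phy, model = "BM"), phy$tip.label)
  expect_equal(blombergK(phy, x),
    as.numeric(picante::Kcalc(x[phy$tip.label], phy)), tolerance = 1e-8)
})

test_that("K over posterior trees: singleton identity, power, p-floor", {
  phy <- simulateTimeTree(12, BirthDeathParams(1.5, 0.25, 1), 3, seed = 11)
  x <- setNames(ape::rTraitCont(phy, model = "BM"), phy$tip.label)
  single <- kOverPosterior(list(phy), x, permutations = 99, seed = 1)
  expect_equal(single@kMean, blombergK(phy, x), tolerance = 1e-12)
  # strong-signal data at 999 permutations bottoms out at p = 0.001
  xs <- setNames(10 * ape::rTraitCont(phy, model = "BM", sigma = 3),
    phy$tip.label)
  trees <- lapply(1:5, function(i) phy)
  res <- kOverPosterior(trees, xs, permutations = 999, seed = 2)
  expect_gte(res@p, 0.001)
  # BM-on-true-topology power check (small n)
  set.seed(12)
  hits <- replicate(10, {
    xb <- setNames(ape::rTraitCont(phy, model = "BM"), phy$tip.label)
    kOverPosterior(list(phy), xb, permutations = 199,
      seed = sample.int(1e6, 1))@p <= 0.05
  })
  expect_gte(mean(hits), 0.6)
})
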