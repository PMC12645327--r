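test_that("construction, reading and round-trips preserve states and annotations", {
  m <- TraitMatrix(rbind(A = c(1L, 0L), B = c(0L, 1L)))
  expect_identical(taxa(m), c("A", "B"))
  expect_identical(dim(traitStates(m)), c(2L, 2L))
  expect_true(all(charWeights(m) == 1))

  csv <- tempfile(fileext = ".csv")
  writeLines("taxon,c1,c2\nA,1,0\nB,0,1", csv)
  m2 <- readTraitMatrix(csv, "csv")
  expect_identical(traitStates(m2), traitStates(m))

  # '?' maps to missing, everything else stays binary
  nex <- tempfile(fileext = ".nex")
  mq <- TraitMatrix(matrix(c(1L, NA, 0L, 1L), 2, 2,
    dimnames = list(c("A", "B"), c("c1", "c2"))))
  writeTraitMatrix(mq, nex, "nexus")
  m3 <- readTraitMatrix(nex, "nexus")
  expect_identical(sum(is.na(traitStates(m3))), 1L)
  expect_identical(unname(traitStates(m3)), unname(traitStates(mq)))

  # full round-trip with annotations, both formats
  ann <- tempfile(fileext = ".csv")
  out <- tempfile(fileext = ".csv")
  mA <- TraitMatrix(matrix(sample(c(0L, 1L, NA), 40, TRUE), 4, 10,
    dimnames = list(paste0("t", 1:4), paste0("c", 1:10))),
    levels = rep(1:2, 5), categories = rep(c("noun", "verb"), 5),
    weights = rep(c(8, 4), 5))
  writeTraitMatrix(mA, out, "csv", annotationPath = ann)
  mB <- readTraitMatrix(out, "csv", annotations = ann)
  expect_identical(traitStates(mB), traitStates(mA))
  expect_identical(charLevels(mB), charLevels(mA))
  expect_identical(charCategories(mB), charCategories(mA))
  expect_identical(charWeights(mB), charWeights(mA))
})

test_that("format and annotation errors are reported with context", {
  csv <- tempfile(fileext = ".csv")
  writeLines("taxon,c1,c2\nA,1,2\nB,0,1", csv)
  expect_error(readTraitMatrix(csv, "csv"), "non-binary symbol")
  csv2 <- tempfile(fileext = ".csv")
  writeLines("taxon,c1\nA,1\nA,0", csv2)
  expect_error(readTraitMatrix(csv2, "csv"), "duplicate taxon")
  m <- TraitMatrix(rbind(A = c(1L, 0L), B = c(0L, 1L)))
  expect_error(attachAnnotations(m,
    data.frame(char_id = "zz", level = 1)), "zz")
})

test_that("annotation fixture reproduces the study's level and category counts", {
  m <- loomLikeFixture()
  ann <- tempfile(fileext = ".csv")
  out <- tempfile(fileext = ".csv")
  writeTraitMatrix(m, out, "csv", annotationPath = ann)
  m2 <- readTraitMatrix(out, "csv", annotations = ann)
  expect_identical(sum(charLevels(m2) == 2L), 102L)
  expect_identical(sum(charLevels(m2) == 4L), 13L)
  expect_identical(sum(charCategories(m2) == "structure"), 159L)
  expect_identical(sum(charCategories(m2) == "simple-patterning"), 27L)
  expect_identical(sum(charCategories(m2) == "complex-patterning"), 30L)
})

test_that("subsetting keeps matching characters and rejects empty selections", {
  phy <- parseTimeTree("((A:1,B:1):1,(C:1,D:1):1);")
  set.seed(7)
  st <- matrix(sample(c(0L, 1L), 400, TRUE), 4, 100,
    dimnames = list(c("A", "B", "C", "D"), paste0("c", 1:100)))
  m <- TraitMatrix(st, levels = rep(c(1L, 2L), c(40, 60)))
  s1 <- subsetCharacters(m, function(a) a$level == 1)
  expect_identical(ncol(traitStates(s1)), 40L)
  expect_identical(taxa(s1), taxa(m))
  expect_error(subsetCharacters(m, function(a) a$level == 5), "empty")

  lm <- loomLikeFixture()
  expect_identical(
    ncol(traitStates(subsetCharacters(lm,
      function(a) a$category == "structure"))), 159L)

  # subsetting == zeroing the non-selected weights in the likelihood
  mod <- CovarionModel(freq = c(0.4, 0.6), alpha = 0.7, switchRate = 0.3,
    overallRate = 0.5)
  w <- ifelse(charLevels(m) == 1, 1, 0)
  expect_equal(totalLogLikelihood(s1, phy, mod),
    totalLogLikelihood(m, phy, mod, weights = w), tolerance = 1e-12)
})

test_that("level weights follow the mapping and integer weights equal duplication", {
  phy <- parseTimeTree("((A:1,B:1):1,(C:1,D:1):1);")
  set.seed(8)
  st <- matrix(sample(c(0L, 1L), 48, TRUE), 4, 12,
    dimnames = list(c("A", "B", "C", "D"), paste0("c", 1:12)))
  m <- TraitMatrix(st, levels = rep(1:4, 3))
  mw <- applyLevelWeights(m, c("1" = 8, "2" = 4, "3" = 2, "4" = 1))
  expect_identical(charWeights(mw), c(8, 4, 2, 1)[charLevels(m)])
  expect_error(applyLevelWeights(m, c("1" = 8)), "level")

  mod <- CovarionModel(freq = c(0.45, 0.55), alpha = 0.6,
    switchRate = 0.4, overallRate = 0.6)
  # all-ones mapping leaves the likelihood untouched
  m1 <- applyLevelWeights(m, c("1" = 1, "2" = 1, "3" = 1, "4" = 1))
  expect_equal(totalLogLikelihood(m1, phy, mod),
    totalLogLikelihood(m, phy, mod), tolerance = 1e-12)
  # weight w == replicating the character w times
  idx <- rep(seq_len(12), charWeights(mw))
  mrep <- TraitMatrix(st[, idx], charIds = paste0("r", seq_along(idx)))
  expect_equal(totalLogLikelihood(mw, phy, mod),
    totalLogLikelihood(mrep, phy, mod), tolerance = 1e-12)
})

test_that("shared-taxon matching restricts, orders, and validates", {
  a <- TraitMatrix(matrix(0L, 5, 3, dimnames = list(paste0("lang", 1:5),
    paste0("c", 1:3))))
  b <- TraitMatrix(matrix(1L, 4, 2, dimnames = list(paste0("loom", 1:4),
    paste0("d", 1:2))))
  mp <- data.frame(a = c("lang3", "lang1", "lang5"),
    b = c("loom2", "loom1", "loom4"))
  mm <- matchSharedTaxa(a, b, mp)
  expect_identical(taxa(mm$a), mp$a)
  expect_identical(taxa(mm$b), mp$b)
  expect_error(matchSharedTaxa(a, b, mp[0, ]), "empty")
  bad <- data.frame(a = "nope", b = "loom1")
  expect_error(matchSharedTaxa(a, b, bad), "nope")
  dup <- data.frame(a = c("lang1", "lang1"), b = c("loom1", "loom2"))
  expect_error(matchSharedTaxa(a, b, dup), "duplicate")
})
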