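quartetNames <- c("P1", "P2", "P3", "O")

test_that("site-pattern sums match hand evaluation and the brute-force oracle", {
  ## hand-evaluated 5-site toy table (geno per species P1,P2,P3,O)
  gm <- toyGenotypeMatrix(rbind(
    c(0, 2, 2, 0),   # pure ABBA: +1 abba
    c(2, 0, 2, 0),   # pure BABA: +1 baba
    c(0, 0, 0, 0),   # monomorphic: nothing
    c(1, 2, 2, 0),   # p = (.5,1,1,0): abba += .5
    c(2, 0, 0, 2)))  # repolarized to (0,1,1,0): abba += 1
  cnt <- sitePatternSums(gm, quartetNames, nBlocks = 2)
  expect_equal(cnt@abba, 2.5)
  expect_equal(cnt@baba, 1)
  expect_equal(cnt@nUsed, 5L)
  expect_equal(sum(cnt@blockAbba), cnt@abba)

  ## outgroup-heterozygous and missing sites are skipped
  gm2 <- toyGenotypeMatrix(rbind(c(0, 2, 2, 1), c(0, NA, 2, 0)))
  expect_equal(sitePatternSums(gm2, quartetNames)@nUsed, 0L)

  ## brute-force equality on a simulated fixture
  gms <- simulateQuartetSites(quartetModel(gamma = 0.25), 1000, seed = 77)
  g <- genotypes(gms)
  g[cbind(sample(1000, 30), sample(4, 30, TRUE))] <- NA
  gms <- GenotypeMatrix(speciesNames(gms), chromosomes(gms),
                        positions(gms), g)
  cnt2 <- sitePatternSums(gms, quartetNames)
  orc <- bruteSitePattern(gms, quartetNames)
  expect_equal(cnt2@abba, orc$abba, tolerance = 1e-12)
  expect_equal(cnt2@baba, orc$baba, tolerance = 1e-12)
  expect_equal(cnt2@nUsed, orc$n)
  expect_error(sitePatternSums(gms, c("P1", "P2", "P3", "P3")), "distinct")
})

test_that("Patterson's D follows its formula and antisymmetry", {
  expect_equal(pattersonD(10, 10), 0)
  expect_equal(pattersonD(3, 1), 0.5)
  expect_true(is.nan(pattersonD(0, 0)))
  gm <- simulateQuartetSites(quartetModel(gamma = 0.2), 5000, seed = 3)
  d12 <- pattersonD(sitePatternSums(gm, quartetNames))
  d21 <- pattersonD(sitePatternSums(gm, c("P2", "P1", "P3", "O")))
  expect_identical(d12, -d21)                     # exact negation
  expect_true(abs(d12) <= 1)
})

test_that("block jackknife matches hand arithmetic and flags degeneracy", {
  ## identical per-block partials: zero variance, unperformable Z
  cEq <- new("SitePatternCounts", abba = 4, baba = 2, nUsed = 100L,
             blockAbba = c(2, 2), blockBaba = c(1, 1),
             quartet = quartetNames)
  expect_true(is.nan(blockJackknife(cEq)$z))

  ## 2-block toy, hand-computed delete-one pseudovalues:
  ## A=4, B=2 -> d = 1/3; d_(1) = (1-1)/2 = 0; d_(2) = (3-1)/4 = 0.5
  ## se = sqrt(1/2 * ((0-.25)^2 + (.5-.25)^2)) = 0.25; z = (1/3)/0.25
  cTwo <- new("SitePatternCounts", abba = 4, baba = 2, nUsed = 100L,
              blockAbba = c(3, 1), blockBaba = c(1, 1),
              quartet = quartetNames)
  jk <- blockJackknife(cTwo)
  expect_equal(jk$d, 1 / 3)
  expect_equal(jk$se, 0.25)
  expect_equal(jk$z, (1 / 3) / 0.25)

  ## fewer than 2 non-empty blocks
  cOne <- new("SitePatternCounts", abba = 4, baba = 2, nUsed = 10L,
              blockAbba = c(4, 0), blockBaba = c(2, 0),
              quartet = quartetNames)
  expect_true(is.nan(blockJackknife(cOne)$z))
})

test_that("f4 ratio is 1 for a perfect donor copy and near 0 under the null", {
  gm <- simulateQuartetSites(quartetModel(gamma = 0), 5000, seed = 11)
  g <- genotypes(gm)
  g[, "P2"] <- g[, "P3"]                          # P2 := copy of P3
  gmCopy <- GenotypeMatrix(speciesNames(gm), chromosomes(gm),
                           positions(gm), g)
  expect_equal(f4AdmixtureRatio(gmCopy, quartetNames), 1)

  gm0 <- simulateQuartetSites(quartetModel(gamma = 0), 50000, seed = 12)
  expect_lt(abs(f4AdmixtureRatio(gm0, quartetNames)), 0.02)

  ## zero denominator (P3 carries no drift relative to P1) is unperformable
  g[, "P3"] <- g[, "P1"]
  gmZero <- GenotypeMatrix(speciesNames(gm), chromosomes(gm),
                           positions(gm), g)
  expect_true(is.nan(suppressMessages(f4AdmixtureRatio(gmZero,
                                                       quartetNames))))
})

test_that("window scan tiles half-open windows and masks, never zero-fills", {
  ## sites only in windows 1 and 3; window 2 must be masked, not 0
  gm <- toyGenotypeMatrix(
    matrix(rep(c(0L, 2L, 2L, 0L), each = 60), ncol = 4),
    pos = as.integer(c(seq(1, 50000, length.out = 30),
                       seq(200001, 250000, length.out = 30))))
  sc <- windowScan(gm, quartetNames, w = 1e5, minSites = 10)
  w <- scanWindows(sc)
  expect_equal(nrow(w), 3L)
  expect_equal(w$start, c(0, 1e5, 2e5))
  expect_true(w$masked[2] && is.na(w$d[2]))
  expect_equal(w$d[c(1, 3)], c(1, 1))

  ## genome-wide null: unmasked window D centred on zero
  m <- quartetModel(t1 = 1, t2 = 2, t3 = 4, gamma = 0)
  sim <- simulateGenomeWithTracts(c(chr1 = 50e6), m, NULL,
                                  siteDensity = 0.01, seed = 31)
  w2 <- scanWindows(windowScan(sim$genotypes, quartetNames))
  expect_lt(abs(mean(w2$d[!w2$masked])), 0.03)
})

test_that("window classification ranks |D| with deterministic tie-breaks", {
  d <- c(0.9, -0.8, 0.1, 0.05, -0.02, 0.3, 0.02, -0.6, 0.15, 0.25)
  sc <- toyScan(d)
  cl <- classifyWindows(sc, 0.3)                  # ceil(0.3*10) = 3
  expect_equal(nrow(cl$selected), 3L)
  expect_equal(sort(cl$selected$d), sort(c(0.9, -0.8, -0.6)))
  expect_equal(cl$positive$d, 0.9)
  expect_equal(sort(cl$negative$d), c(-0.8, -0.6))

  ## exactly 5 of 100, and an all-positive selection leaves D<0 empty
  sc100 <- toyScan(seq(0.01, 1, length.out = 100))
  cl100 <- classifyWindows(sc100, 0.05)
  expect_equal(nrow(cl100$selected), 5L)
  expect_equal(nrow(cl100$negative), 0L)

  ## ties at the cutoff resolved by (chrom, start) ascending
  scTie <- toyScan(c(0.5, 0.5, 0.5, 0.1))
  clTie <- classifyWindows(scTie, 0.5)            # take 2 of the three 0.5s
  expect_equal(clTie$selected$start, c(0, 1e5))
  expect_error(classifyWindows(toyScan(c(NA, NA),
                                       masked = c(TRUE, TRUE)), 0.1),
               "masked")
})

test_that("interval gaps use bp coordinates and a calibrated one-sided test", {
  sc <- toyScan(rep(0.5, 10))
  adj <- scanWindows(sc)[1:2, ]                   # [0,100k) + [100k,200k)
  apart <- scanWindows(sc)[c(1, 4), ]             # [0,100k) + [300k,400k)
  ia1 <- intervalAnalysis(sc, adj, nControl = 10, seed = 1)
  expect_equal(gapLengths(ia1), 0)
  ia2 <- intervalAnalysis(sc, apart, nControl = 10, seed = 1)
  expect_equal(gapLengths(ia2), 2e5)
  expect_error(intervalAnalysis(sc, adj[1, , drop = FALSE]),
               "unperformable")

  ## the set tested against itself as control gives p near 0.5
  set.seed(6)
  maskBig <- sample(c(TRUE, FALSE), 300, TRUE)
  scBig <- toyScan(rnorm(300), masked = maskBig)
  all <- scanWindows(scBig)[!maskBig, ]
  iaSelf <- intervalAnalysis(scBig, all, nControl = sum(!maskBig),
                             seed = 2)
  expect_identical(sort(gapLengths(iaSelf)),
                   sort(controlGapLengths(iaSelf)))
  expect_lt(abs(iaSelf@p - 0.5), 0.05)
})

test_that("f-branch marks unperformable cells NaN and is quiet under no gene flow", {
  tree3 <- ape::read.tree(text = "(((P1:1,P2:1):1,P3:2):2,O:4);")
  gm <- simulateQuartetSites(quartetModel(gamma = 0), 30000, seed = 41)
  fb <- suppressMessages(fBranch(tree3, gm, "O"))
  ## branch above (P1,P2): its sister is P3 alone, so donor P3 has no A
  expect_true(all(is.nan(fb["A", ])))
  ## diagonal-like cells (C inside the branch) are NaN
  expect_true(is.nan(fb["P1", "P1"]))
  ## everything defined is small without gene flow
  expect_true(all(fb[is.finite(fb)] <= 0.02))
  expect_error(fBranch(ape::read.tree(text = "(P1:1,P2:1,P3:1);"), gm, "O"),
               "rooted")
})
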