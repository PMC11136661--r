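## small raster stack built directly from matrices
rasterFrom <- function(m) EnvRaster(m, xll = 0, yll = 0, cellsize = 1)

test_that("variable selection enforces the pairwise correlation ceiling", {
  set.seed(4)
  n <- 300
  a <- rnorm(n); b <- a + rnorm(n, sd = 0.01)    # near-duplicate pair
  c3 <- rnorm(n)
  sel <- selectVariables(data.frame(a = a, b = b, c = c3))
  expect_length(sel$selected, 2)
  expect_true("c" %in% sel$selected)
  expect_true(sum(c("a", "b") %in% sel$selected) == 1)

  ## mutually independent variables are all retained
  ind <- as.data.frame(matrix(rnorm(n * 5), n, 5))
  expect_length(selectVariables(ind)$selected, 5)

  ## block-correlated structure: survivors satisfy max |r| < 0.8
  z1 <- rnorm(n); z2 <- rnorm(n)
  blk <- data.frame(v1 = z1, v2 = z1 + rnorm(n, sd = 0.3),
                    v3 = z1 + rnorm(n, sd = 0.3),
                    v4 = z2, v5 = z2 + rnorm(n, sd = 0.3))
  out <- selectVariables(blk)
  expect_lt(max(abs(out$correlation[upper.tri(out$correlation)])), 0.8)

  ## constant variable dropped first, with a message
  expect_message(selectVariables(data.frame(k = rep(1, n), x = a, y = c3)),
                 "constant")
})

test_that("environment extraction is nearest-cell with nodata exclusion", {
  m <- matrix(1:9, 3, 3)                 # row 1 = north
  m[2, 2] <- NA
  r <- rasterFrom(m)
  occ <- data.frame(species = "s",
                    lon = c(0.5, 2.5, 1.5, 9.0),
                    lat = c(2.5, 0.5, 1.5, 1.0))
  env <- suppressMessages(extractEnv(list(v = r), occ))
  ## cell centres: (0.5, 2.5) is row 1 col 1 -> 1; (2.5, 0.5) row 3 col 3 -> 9
  expect_equal(env$v, c(1, 9))
  expect_equal(attr(env, "nExcluded"), 2L)      # nodata centre + off-raster
  expect_error(suppressMessages(
    extractEnv(list(v = r), data.frame(species = "s", lon = 99, lat = 99))),
    "off the raster")
})

test_that("ecological valence is the min-max envelope", {
  env <- data.frame(species = c("s", "s", "s", "t"),
                    v = c(3, 7, 5, 2))
  val <- ecologicalValence(env)
  expect_equal(val$min[val$species == "s"], 3)
  expect_equal(val$max[val$species == "s"], 7)
  ## a single occurrence gives a degenerate range
  expect_equal(val$min[val$species == "t"], val$max[val$species == "t"])
})

test_that("habitat superimposition counts in-range layers inclusively", {
  m1 <- matrix(c(1, 2, 3, 4), 2, 2)
  m2 <- matrix(c(10, 10, 10, 99), 2, 2)
  rs <- list(v1 = rasterFrom(m1), v2 = rasterFrom(m2))
  val <- data.frame(species = "s", variable = c("v1", "v2"),
                    min = c(1, 10), max = c(4, 10))
  hab <- superimposeHabitat(rs, val, "s")
  ## endpoint-inclusive: v1 in range everywhere; v2 fails one cell
  expect_equal(rasterValues(hab$count), matrix(c(2, 2, 2, 1), 2, 2))
  expect_equal(rasterValues(hab$habitat), matrix(c(1, 1, 1, 0), 2, 2))

  ## widening a range never shrinks the habitat (monotone inclusion)
  val2 <- val; val2$max[2] <- 99
  hab2 <- superimposeHabitat(rs, val2, "s")
  expect_true(all(rasterValues(hab2$habitat) >= rasterValues(hab$habitat)))

  ## nodata propagates
  m1na <- m1; m1na[1, 1] <- NA
  habNA <- superimposeHabitat(list(v1 = rasterFrom(m1na),
                                   v2 = rs$v2), val, "s")
  expect_true(is.na(rasterValues(habNA$count)[1, 1]))
})

test_that("PCA niche space standardises, centres and exposes collinearity", {
  set.seed(8)
  m1 <- matrix(rnorm(2500), 50, 50)
  m2 <- matrix(rnorm(2500), 50, 50)
  rs <- list(a = rasterFrom(m1), b = rasterFrom(m2))
  sp <- pcaNicheSpace(rs)
  ev <- sp@sdev^2 / sum(sp@sdev^2)
  expect_lt(abs(ev[1] - 0.5), 0.05)              # isotropic cloud
  ## the background mean projects to the origin
  centreScore <- projectNiche(sp, as.data.frame(t(sp@center)))
  expect_lt(max(abs(centreScore)), 1e-10)
  ## a duplicated variable collapses PC2 of the pair
  spDup <- pcaNicheSpace(list(a = rasterFrom(m1), b = rasterFrom(m1)))
  evDup <- spDup@sdev^2 / sum(spDup@sdev^2)
  expect_lt(evDup[2], 1e-10)
})

test_that("niche densities are normalised with sensible mass placement", {
  set.seed(9)
  bg <- matrix(rnorm(4000), ncol = 2)
  sp <- new("NicheSpace", center = c(a = 0, b = 0), scale = c(a = 1, b = 1),
            rotation = diag(2), sdev = c(1, 1), bgScores = bg,
            extent = c(-4, 4, -4, 4))
  rownames(sp@rotation) <- c("a", "b")
  sc <- matrix(rnorm(200, sd = 0.5), ncol = 2)
  dg <- nicheDensity(sc, sp)
  expect_equal(sum(densityValues(dg)), 1, tolerance = 1e-12)
  expect_true(all(densityValues(dg) >= 0))

  ## a tight cluster puts the modal cell at its centroid
  tight <- matrix(rnorm(100, mean = 2, sd = 0.05), ncol = 2)
  dgT <- nicheDensity(tight, sp, bandwidth = c(0.3, 0.3))
  ij <- which(densityValues(dgT) == max(densityValues(dgT)),
              arr.ind = TRUE)
  expect_lt(abs(dgT@x[ij[1]] - 2), 0.2)
  expect_lt(abs(dgT@y[ij[2]] - 2), 0.2)

  ## two equal separated clusters carry comparable mass
  two <- rbind(matrix(rnorm(400, -2, 0.2), ncol = 2),
               matrix(rnorm(400, 2, 0.2), ncol = 2))
  dg2 <- nicheDensity(two, sp, bandwidth = c(0.3, 0.3))
  z <- densityValues(dg2)
  left <- sum(z[dg2@x < 0, ]); right <- sum(z[dg2@x > 0, ])
  expect_lt(abs(left - right) / max(left, right), 0.1)

  ## zero-variance cloud: all mass in one cell
  dg0 <- nicheDensity(matrix(c(1, 1, 1, 1), 2, 2), sp)
  expect_equal(sum(densityValues(dg0) > 0), 1L)
})

test_that("Schoener's D has its endpoint, symmetry and bound properties", {
  z1 <- matrix(c(0.5, 0.5, 0, 0), 2, 2)
  z2 <- matrix(c(0.5, 0, 0.5, 0), 2, 2)
  expect_equal(schoenerD(z1, z1), 1)
  expect_equal(schoenerD(z1, z2), 0.5)
  zd1 <- matrix(c(1, 0, 0, 0), 2, 2); zd2 <- matrix(c(0, 0, 0, 1), 2, 2)
  expect_equal(schoenerD(zd1, zd2), 0)
  set.seed(10)
  for (i in 1:5) {
    a <- matrix(runif(16), 4); a <- a / sum(a)
    b <- matrix(runif(16), 4); b <- b / sum(b)
    expect_identical(schoenerD(a, b), schoenerD(b, a))
    expect_gte(schoenerD(a, b), 0)
    expect_lte(schoenerD(a, b), 1)
  }
  expect_error(schoenerD(z1, matrix(1, 3, 3)), "shape")
})

test_that("equivalency test: null calibration, separation, and uniform p", {
  set.seed(11)
  bg <- matrix(rnorm(2000), ncol = 2)
  sp <- new("NicheSpace", center = c(a = 0, b = 0), scale = c(a = 1, b = 1),
            rotation = structure(diag(2), dimnames = list(c("a", "b"),
                                                          NULL)),
            sdev = c(1, 1), bgScores = bg, extent = c(-4, 4, -4, 4))
  ## two samples from the identical distribution: rarely significant
  pvals <- vapply(1:20, function(s) {
    set.seed(500 + s)
    s1 <- matrix(rnorm(60), ncol = 2)
    s2 <- matrix(rnorm(60), ncol = 2)
    equivalencyTest(s1, s2, sp, nReps = 99, seed = s, R = 40)$p
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)

  ## fully separated clusters: the smallest attainable p
  s1 <- matrix(rnorm(60, -2.5, 0.1), ncol = 2)
  s2 <- matrix(rnorm(60, 2.5, 0.1), ncol = 2)
  eq <- equivalencyTest(s1, s2, sp, nReps = 99, seed = 1, R = 40)
  expect_equal(eq$p, 1 / 100)
  expect_equal(eq$nReps, 99)

  ## p is approximately uniform under the null (KS at alpha = 0.01)
  pU <- vapply(1:200, function(s) {
    set.seed(900 + s)
    s1 <- matrix(rnorm(40), ncol = 2)
    s2 <- matrix(rnorm(40), ncol = 2)
    equivalencyTest(s1, s2, sp, nReps = 49, seed = s, R = 30)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pU, "punif")$p.value), 0.01)
})

test_that("similarity test reports both directions against the background", {
  set.seed(12)
  bg <- matrix(rnorm(2000), ncol = 2)
  sp <- new("NicheSpace", center = c(a = 0, b = 0), scale = c(a = 1, b = 1),
            rotation = structure(diag(2), dimnames = list(c("a", "b"),
                                                          NULL)),
            sdev = c(1, 1), bgScores = bg, extent = c(-4, 4, -4, 4))
  ## identical tight clusters against a broad background: small p both ways
  s1 <- matrix(rnorm(80, 1.5, 0.1), ncol = 2)
  st <- similarityTest(s1, s1 + rnorm(80, sd = 0.05), sp, nReps = 99,
                       seed = 2, R = 40)
  expect_named(st$p, c("1", "2"))
  expect_lte(st$p[["1"]], 0.05)
  expect_lte(st$p[["2"]], 0.05)

  ## a species that is itself uniform over the background is unremarkable
  pv <- vapply(1:10, function(s) {
    set.seed(700 + s)
    u <- bg[sample.int(nrow(bg), 50), ]
    similarityTest(matrix(rnorm(60), ncol = 2), u, sp, nReps = 49,
                   seed = s, R = 30)$p[["2"]]
  }, numeric(1))
  expect_gte(mean(pv > 0.05), 0.6)

  ## background smaller than the sample triggers with-replacement sampling
  small <- bg[1:5, ]
  expect_message(similarityTest(s1, s1, sp, background = small, nReps = 9,
                                seed = 3, R = 20), "replacement")
})

test_that("land area is non-increasing in sea level with analytic geometry", {
  isl <- simulateIslandRasters(gridSize = 100, peak = 1000, noiseAmp = 0,
                               seed = 2)
  lv <- seq(-100, 1100, length.out = 50)
  ac <- landArea(isl$elevation, lv)
  expect_true(all(diff(ac$nCells) <= 0))
  expect_equal(ac$nCells[1], sum(!is.na(rasterValues(isl$elevation))))
  expect_equal(ac$nCells[50], 0)
  expect_equal(landArea(isl$elevation, 0)$pctChange, 0)
  ## half-peak sea level leaves the analytic half-radius disc
  radius <- 0.4 * 100
  aHalf <- landArea(isl$elevation, 500)$nCells
  expect_lt(abs(aHalf - pi * (radius / 2)^2) / (pi * (radius / 2)^2), 0.02)
  ## exact agreement with a brute-force cell count
  v <- rasterValues(isl$elevation)
  expect_equal(ac$nCells,
               vapply(lv, function(s) sum(v > s, na.rm = TRUE), numeric(1)))
})
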