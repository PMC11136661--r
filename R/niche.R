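## Ecological valence envelopes, bioclimatic layer superimposition, PCA
## niche space with kernel densities and Schoener's D, the
## equivalency/similarity randomization tests, and land-area-vs-sea-level
## curves.

#' Select weakly correlated environmental variables
#'
#' Greedy elimination: constant variables (undefined r) are dropped first,
#' then the variable with the largest mean absolute pairwise correlation is
#' dropped repeatedly until all pairwise |r| < `rMax` (the Pearson r < 0.8
#' selection rule by default).
#'
#' @param envTable numeric data.frame/matrix, rows = samples (e.g. cells),
#'   columns = variables.
#' @param rMax correlation ceiling (default 0.8).
#' @return list(selected = surviving variable names, correlation = their
#'   correlation matrix, dropped = names in drop order).
#' @export
selectVariables <- function(envTable, rMax = 0.8) {
  m <- as.matrix(envTable)
  if (ncol(m) < 2 || nrow(m) < 3)
    stop("need at least 2 variables and 3 rows")
  keep <- colnames(m)
  const <- keep[apply(m, 2, function(x) stats::sd(x, na.rm = TRUE) == 0)]
  if (length(const)) {
    message("selectVariables: dropping constant variable(s): ",
            paste(const, collapse = ", "))
    keep <- setdiff(keep, const)
  }
  dropped <- const
  repeat {
    r <- cor(m[, keep, drop = FALSE], use = "pairwise.complete.obs")
    diag(r) <- 0
    if (length(keep) < 2 || max(abs(r)) < rMax) break
    worst <- keep[which.max(rowMeans(abs(r)))]
    dropped <- c(dropped, worst)
    keep <- setdiff(keep, worst)
  }
  r <- cor(m[, keep, drop = FALSE], use = "pairwise.complete.obs")
  list(selected = keep, correlation = r, dropped = dropped)
}

.cellIndex <- function(raster, lon, lat) {
  col <- floor((lon - raster@xll) / raster@cellsize) + 1
  row <- raster@nrows - floor((lat - raster@yll) / raster@cellsize)
  ok <- col >= 1 & col <= raster@ncols & row >= 1 & row <= raster@nrows
  list(row = row, col = col, ok = ok)
}

#' Extract environmental values at occurrence points
#'
#' Nearest-cell extraction from a shared-grid raster stack.  Points that
#' fall off the raster or on nodata in any layer are excluded and counted
#' in the `nExcluded` attribute.
#'
#' @param rasters named list of [EnvRaster-class] (same grid).
#' @param occurrences data.frame with columns species, lon, lat.
#' @return data.frame: species plus one column per raster variable.
#' @export
extractEnv <- function(rasters, occurrences) {
  r1 <- rasters[[1]]
  ci <- .cellIndex(r1, occurrences$lon, occurrences$lat)
  vals <- sapply(rasters, function(r) {
    v <- rep(NA_real_, nrow(occurrences))
    v[ci$ok] <- r@values[cbind(ci$row[ci$ok], ci$col[ci$ok])]
    v
  })
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1,
                                         dimnames = list(NULL, names(rasters)))
  keep <- ci$ok & rowSums(is.na(vals)) == 0
  nExcluded <- sum(!keep)
  if (nExcluded > 0)
    message("extractEnv: excluded ", nExcluded,
            " point(s) off-raster or on nodata")
  if (!any(keep)) stop("all points fall off the raster or on nodata")
  out <- data.frame(species = occurrences$species[keep],
                    vals[keep, , drop = FALSE])
  names(out) <- c("species", names(rasters))
  attr(out, "nExcluded") <- nExcluded
  out
}

#' Ecological valence (amplitude) table
#'
#' The tolerance range of each species for each variable: the range
#' between the lowest and highest values at its occurrences.
#'
#' @param envTable output of [extractEnv()] (species + variable columns).
#' @return data.frame: species, variable, min, max.
#' @export
ecologicalValence <- function(envTable) {
  vars <- setdiff(names(envTable), "species")
  out <- expand.grid(species = unique(envTable$species), variable = vars,
                     stringsAsFactors = FALSE)
  out$min <- NA_real_; out$max <- NA_real_
  for (i in seq_len(nrow(out))) {
    v <- envTable[envTable$species == out$species[i], out$variable[i]]
    out$min[i] <- min(v)
    out$max[i] <- max(v)
  }
  out
}

#' Superimpose in-range bioclimatic layers into a habitat map
#'
#' Per variable, a binary in-range layer (valence min <= value <= max,
#' endpoints inclusive); the overlap count is their sum and the habitat
#' mask comprises the cells where every variable is in range (the maximal
#' overlap count).  Nodata propagates.
#'
#' @param rasters named list of [EnvRaster-class].
#' @param valence data.frame from [ecologicalValence()].
#' @param species which species' valence to use.
#' @return list(count = overlap-count [EnvRaster-class], habitat = 0/1
#'   mask [EnvRaster-class], nVars).
#' @export
superimposeHabitat <- function(rasters, valence, species) {
  val <- valence[valence$species == species, , drop = FALSE]
  vars <- val$variable
  miss <- setdiff(vars, names(rasters))
  if (length(miss)) stop("no raster for valence variable(s): ",
                         paste(miss, collapse = ", "))
  r1 <- rasters[[vars[1]]]
  count <- matrix(0, r1@nrows, r1@ncols)
  nodata <- matrix(FALSE, r1@nrows, r1@ncols)
  for (i in seq_along(vars)) {
    v <- rasters[[vars[i]]]@values
    nodata <- nodata | is.na(v)
    inRange <- !is.na(v) & v >= val$min[i] & v <= val$max[i]
    count <- count + inRange
  }
  count[nodata] <- NA
  habitat <- (count == length(vars)) * 1
  habitat[nodata] <- NA
  list(count = EnvRaster(count, r1@xll, r1@yll, r1@cellsize, r1@nodata),
       habitat = EnvRaster(habitat, r1@xll, r1@yll, r1@cellsize,
                           r1@nodata),
       nVars = length(vars))
}

#' Fit the PCA environmental niche space on background cells
#'
#' Variables are standardised over the cells where every layer has data
#' (the land background); the PCA is fitted there and any occurrence can
#' then be projected to (PC1, PC2) with [projectNiche()].
#'
#' @param rasters named list of [EnvRaster-class]; @param vars variables to
#'   use (default all).
#' @return A [NicheSpace-class].
#' @export
pcaNicheSpace <- function(rasters, vars = names(rasters)) {
  if (length(vars) < 2) stop("need at least 2 variables")
  m <- sapply(rasters[vars], function(r) as.vector(r@values))
  m <- m[rowSums(is.na(m)) == 0, , drop = FALSE]
  if (nrow(m) < length(vars)) stop("fewer complete land cells than variables")
  pc <- prcomp(m, center = TRUE, scale. = TRUE)
  sc <- pc$x[, 1:2, drop = FALSE]
  pad <- 0.05 * c(diff(range(sc[, 1])), diff(range(sc[, 2])))
  extent <- c(min(sc[, 1]) - pad[1], max(sc[, 1]) + pad[1],
              min(sc[, 2]) - pad[2], max(sc[, 2]) + pad[2])
  new("NicheSpace", center = pc$center, scale = pc$scale,
      rotation = pc$rotation, sdev = pc$sdev, bgScores = sc,
      extent = extent)
}

#' Project environmental values into a fitted niche space
#'
#' @param space a [NicheSpace-class]; @param envTable data.frame holding
#'   the space's variables (extra columns such as species are ignored).
#' @return matrix of (PC1, PC2) scores.
#' @export
projectNiche <- function(space, envTable) {
  vars <- rownames(space@rotation)
  m <- as.matrix(envTable[, vars, drop = FALSE])
  m <- scale(m, center = space@center, scale = space@scale)
  m %*% space@rotation[, 1:2, drop = FALSE]
}

#' Kernel density of occurrences in niche space
#'
#' Gaussian KDE on an R x R grid spanning the background extent of the
#' niche space, normalised to sum to 1.  Bandwidths default to the normal
#' reference (plug-in) rule per axis; a zero-variance point cloud puts all
#' mass in the single nearest cell.
#'
#' @param scores matrix of (PC1, PC2) scores (>= 1 point).
#' @param space a [NicheSpace-class] (defines the shared grid extent).
#' @param R grid resolution (default 100).
#' @param bandwidth optional numeric(2) KDE bandwidths.
#' @return A [DensityGrid-class].
#' @export
nicheDensity <- function(scores, space, R = 100, bandwidth = NULL) {
  ext <- space@extent
  gx <- seq(ext[1], ext[2], length.out = R)
  gy <- seq(ext[3], ext[4], length.out = R)
  if (is.null(bandwidth)) {
    bandwidth <- c(MASS::bandwidth.nrd(scores[, 1]),
                   MASS::bandwidth.nrd(scores[, 2]))
  }
  if (nrow(scores) < 2 || any(bandwidth <= 0)) {
    ## degenerate cloud: all mass in the nearest cell to the centroid
    z <- matrix(0, R, R)
    i <- which.min(abs(gx - mean(scores[, 1])))
    j <- which.min(abs(gy - mean(scores[, 2])))
    z[i, j] <- 1
    return(new("DensityGrid", z = z, x = gx, y = gy,
               bandwidth = c(0, 0)))
  }
  k <- MASS::kde2d(scores[, 1], scores[, 2], h = bandwidth, n = R,
                   lims = ext)
  new("DensityGrid", z = k$z / sum(k$z), x = k$x, y = k$y,
      bandwidth = bandwidth)
}

#' Schoener's D niche overlap
#'
#' D = 1 - 0.5 * sum |z1 - z2| over the shared grid: 0 means no overlap,
#' 1 complete overlap.  Symmetric in its arguments.
#'
#' @param z1,z2 [DensityGrid-class] objects (or normalised matrices) on
#'   the same grid.
#' @return D in [0, 1].
#' @export
schoenerD <- function(z1, z2) {
  if (is(z1, "DensityGrid")) z1 <- z1@z
  if (is(z2, "DensityGrid")) z2 <- z2@z
  if (!all(dim(z1) == dim(z2))) stop("density grids differ in shape")
  1 - 0.5 * sum(abs(z1 - z2))
}

.densityFromScores <- function(scores, space, R, bandwidth)
  nicheDensity(scores, space, R = R, bandwidth = bandwidth)

#' Niche equivalency randomization test
#'
#' Observed Schoener's D between the two species' densities is compared to
#' a null in which the pooled occurrences are randomly reassigned to the
#' two species (sample sizes preserved); p = (#{D_null <= D_obs} + 1) /
#' (nReps + 1), so a low p means the two niches overlap less than
#' equivalent ones would.
#'
#' @param scores1,scores2 (PC1, PC2) score matrices of the two species.
#' @param space a [NicheSpace-class]; @param nReps replicates (default
#'   1000); @param seed RNG seed; @param R,bandwidth passed to
#'   [nicheDensity()].
#' @return list(d, p, nReps, seed).
#' @export
equivalencyTest <- function(scores1, scores2, space, nReps = 1000,
                            seed = NULL, R = 100, bandwidth = NULL) {
  stopifnot(nrow(scores1) >= 2, nrow(scores2) >= 2)
  .setSeed(seed)
  dObs <- schoenerD(.densityFromScores(scores1, space, R, bandwidth),
                    .densityFromScores(scores2, space, R, bandwidth))
  pooled <- rbind(scores1, scores2)
  n1 <- nrow(scores1)
  dNull <- vapply(seq_len(nReps), function(i) {
    idx <- sample.int(nrow(pooled), n1)
    schoenerD(.densityFromScores(pooled[idx, , drop = FALSE], space, R,
                                 bandwidth),
              .densityFromScores(pooled[-idx, , drop = FALSE], space, R,
                                 bandwidth))
  }, numeric(1))
  list(d = dObs, p = (sum(dNull <= dObs) + 1) / (nReps + 1),
       nReps = nReps,
       seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Niche similarity randomization test
#'
#' The null replaces one species' occurrences by points drawn uniformly
#' from the background cells and recomputes D; both directions are
#' reported.  p = (#(D_null >= D_obs) + 1) / (nReps + 1): a low p means
#' the two niches overlap more than a randomly placed niche would, i.e.
#' they are more similar than the background expectation.  When the
#' background holds fewer cells than the sample size, sampling falls back
#' to with-replacement (logged).
#'
#' @param scores1,scores2 (PC1, PC2) score matrices.
#' @param space a [NicheSpace-class]; @param background matrix of
#'   background-cell scores (default the space's land cells).
#' @param nReps replicates (default 1000); @param seed RNG seed;
#' @param R,bandwidth passed to [nicheDensity()].
#' @return list(d, p = c(`1`, `2`) for randomizing species 1 and 2,
#'   nReps, seed).
#' @export
similarityTest <- function(scores1, scores2, space,
                           background = space@bgScores, nReps = 1000,
                           seed = NULL, R = 100, bandwidth = NULL) {
  if (nrow(background) == 0) stop("empty background")
  .setSeed(seed)
  dObs <- schoenerD(.densityFromScores(scores1, space, R, bandwidth),
                    .densityFromScores(scores2, space, R, bandwidth))
  oneDirection <- function(fixed, nRandom) {
    replace <- nrow(background) < nRandom
    if (replace)
      message("similarityTest: background smaller than sample; ",
              "sampling with replacement")
    zFixed <- .densityFromScores(fixed, space, R, bandwidth)
    dNull <- vapply(seq_len(nReps), function(i) {
      idx <- sample.int(nrow(background), nRandom, replace = replace)
      schoenerD(zFixed,
                .densityFromScores(background[idx, , drop = FALSE], space,
                                   R, bandwidth))
    }, numeric(1))
    (sum(dNull >= dObs) + 1) / (nReps + 1)
  }
  p <- c(`1` = oneDirection(scores2, nrow(scores1)),
         `2` = oneDirection(scores1, nrow(scores2)))
  list(d = dObs, p = p, nReps = nReps,
       seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Island land area under a sweep of sea levels
#'
#' Land is every non-nodata cell with elevation strictly greater than the
#' sea level (shoreline cells exactly at the level count as sea); area is
#' the cell count times cellsize^2, with percent change relative to the
#' area at the `baseline` level.
#'
#' @param elevation an [EnvRaster-class]; @param levels numeric sea levels
#'   (same units as elevation); @param baseline reference level (default 0).
#' @return data.frame: level, nCells, area, pctChange.
#' @export
landArea <- function(elevation, levels, baseline = 0) {
  v <- elevation@values
  countAt <- function(s) sum(v > s, na.rm = TRUE)
  n <- vapply(levels, countAt, numeric(1))
  n0 <- countAt(baseline)
  data.frame(level = levels, nCells = n,
             area = n * elevation@cellsize^2,
             pctChange = 100 * (n - n0) / n0)
}
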