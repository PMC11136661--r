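## Seeded generators that emulate the data structure the analyses assume:
## multispecies-coalescent genotypes with optional introgression, genomes
## with planted low-heterozygosity tracts, island-shaped rasters with
## smooth bioclim-like fields, and occurrences drawn from known tolerance
## ranges.  All are pure functions of (configuration, seed).

.setSeed <- function(seed) if (!is.null(seed)) set.seed(seed)

## Decompose an ultrametric species tree (branch lengths in coalescent
## units) into the population-merge schedule of the structured coalescent.
.treeEpochs <- function(tree) {
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  ntip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  tmax <- max(depth[seq_len(ntip)])
  if (max(abs(depth[seq_len(ntip)] - tmax)) > 1e-8 * (1 + tmax))
    stop("species tree must be ultrametric (tips at time 0)")
  nodeTime <- tmax - depth            # time before present of every node
  internal <- (ntip + 1):(ntip + tree$Nnode)
  ord <- internal[order(nodeTime[internal])]
  children <- lapply(ord, function(v) tree$edge[tree$edge[, 1] == v, 2])
  list(ntip = ntip, nodeTime = nodeTime,
       tipPop = seq_len(ntip) - 1L,       # population = branch above node
       eventTime = nodeTime[ord],
       eventFrom = lapply(children, function(ch) as.integer(ch - 1L)),
       eventTo = as.integer(ord - 1L))
}

## Branch (population id, 0-based) above the donor's ancestry at time t.
.donorPopAt <- function(tree, epochs, donor, t) {
  v <- match(donor, tree$tip.label)
  if (is.na(v)) stop("donor species not in tree: ", donor)
  repeat {
    parent <- tree$edge[tree$edge[, 2] == v, 1]
    if (length(parent) == 0)
      stop("introgression time lies above the root")
    if (epochs$nodeTime[parent] > t) return(as.integer(v - 1L))
    v <- parent
  }
}

#' Simulate unlinked biallelic sites on a species tree under the MSC
#'
#' Per site, one haploid lineage per species coalesces under the structured
#' (multispecies) coalescent with optional single-pulse introgression, one
#' mutation is placed uniformly on the gene tree (infinite sites), and the
#' site is emitted as a homozygous diploid genotype (0/2) per species.
#'
#' @param tree rooted ultrametric `phylo`, branch lengths in coalescent
#'   units; tip labels name the species.
#' @param nSites number of sites (> 0).
#' @param gamma per-site introgression probability: scalar or
#'   length-`nSites` vector.
#' @param donor,recipient species labels of the gene-flow edge (forwards in
#'   time donor -> recipient); `NULL` for no introgression.
#' @param tMig introgression time (coalescent units before present).
#' @param seed RNG seed (optional).
#' @param chrom chromosome label; @param positions optional 1-based site
#'   positions (default 1..nSites).
#' @return A [GenotypeMatrix-class] with species ordered as `tree$tip.label`.
#' @export
simulateTreeSites <- function(tree, nSites, gamma = 0, donor = NULL,
                              recipient = NULL, tMig = 0, seed = NULL,
                              chrom = "chr1", positions = NULL) {
  if (nSites <= 0) stop("nSites must be positive")
  .setSeed(seed)
  ep <- .treeEpochs(tree)
  migTip <- -1L
  migPop <- 0L
  if (!is.null(donor) && !is.null(recipient) && any(gamma > 0)) {
    migTip <- as.integer(match(recipient, tree$tip.label) - 1L)
    if (is.na(migTip)) stop("recipient species not in tree: ", recipient)
    migPop <- .donorPopAt(tree, ep, donor, tMig)
  }
  der <- simulate_msc_sites_cpp(ep$ntip, ep$tipPop, ep$eventTime,
                                ep$eventFrom, ep$eventTo, as.numeric(gamma),
                                as.numeric(tMig), migTip, migPop,
                                as.integer(nSites))
  if (is.null(positions)) positions <- seq_len(nSites)
  GenotypeMatrix(tree$tip.label, rep(chrom, nSites), positions, 2L * der)
}

#' Species tree implied by a QuartetModel
#'
#' @param model a [QuartetModel-class].
#' @return A rooted ultrametric `phylo` (((P1,P2),P3),O) with branch
#'   lengths in coalescent units.
#' @export
quartetTree <- function(model) {
  ape::read.tree(text = sprintf(
    "(((P1:%.10g,P2:%.10g):%.10g,P3:%.10g):%.10g,O:%.10g);",
    model@t1, model@t1, model@t2 - model@t1, model@t2,
    model@t3 - model@t2, model@t3))
}

#' Simulate quartet genotypes (P1, P2, P3, O)
#'
#' Wrapper around [simulateTreeSites()] for the quartet model: with
#' probability `gamma` per site the recipient lineage traces into the donor
#' population at `tMig` (direction `"P3->P2"` means P3 is the donor).
#'
#' @param model a [QuartetModel-class]; @param nSites sites; @param seed
#'   RNG seed; @param chrom,positions as in [simulateTreeSites()].
#' @param gamma optional per-site override of `model@gamma` (scalar or
#'   vector), used by the tract simulator.
#' @return A [GenotypeMatrix-class] with species P1, P2, P3, O.
#' @export
simulateQuartetSites <- function(model, nSites, seed = NULL, chrom = "chr1",
                                 positions = NULL, gamma = NULL) {
  stopifnot(is(model, "QuartetModel"))
  if (is.null(gamma)) gamma <- model@gamma
  dr <- strsplit(model@direction, "->", fixed = TRUE)[[1]]
  simulateTreeSites(quartetTree(model), nSites, gamma = gamma,
                    donor = dr[1], recipient = dr[2], tMig = model@tMig,
                    seed = seed, chrom = chrom, positions = positions)
}

#' Simulate a multi-chromosome quartet genome with introgression tracts
#'
#' Sites outside tracts use the model's base `gamma` (usually 0); inside a
#' tract the per-site introgression probability is the tract's
#' `gamma_local`.  Tract structure is imposed directly on unlinked sites:
#' the spatial clustering of signal is what the window scan and
#' interval-length analysis consume.
#'
#' @param chromLengths named integer vector of chromosome lengths (bp).
#' @param model base [QuartetModel-class].
#' @param tracts `GRanges` with an mcols column `gamma` (1-based closed
#'   coordinates), or NULL for none; tracts must not overlap.
#' @param siteDensity expected sites per bp (default 0.001).
#' @param seed RNG seed.
#' @return list with `genotypes` (a [GenotypeMatrix-class]) and `truth`
#'   (the tract `GRanges`).
#' @export
simulateGenomeWithTracts <- function(chromLengths, model, tracts = NULL,
                                     siteDensity = 0.001, seed = NULL) {
  stopifnot(is(model, "QuartetModel"))
  .setSeed(seed)
  if (!is.null(tracts)) {
    if (!is(tracts, "GRanges")) stop("tracts must be a GRanges")
    if (is.null(tracts$gamma)) stop("tracts need an mcols column 'gamma'")
    if (length(GenomicRanges::reduce(tracts)) != length(tracts))
      stop("overlapping tracts")
  }
  dr <- strsplit(model@direction, "->", fixed = TRUE)[[1]]
  tree <- quartetTree(model)
  chroms <- names(chromLengths)
  if (is.null(chroms)) chroms <- paste0("chr", seq_along(chromLengths))
  parts <- vector("list", length(chromLengths))
  for (k in seq_along(chromLengths)) {
    L <- chromLengths[[k]]
    n <- max(2L, round(L * siteDensity))
    pos <- sort(sample.int(L, n))
    g <- rep(model@gamma, n)
    if (!is.null(tracts)) {
      tr <- tracts[as.character(GenomicRanges::seqnames(tracts)) == chroms[k]]
      for (i in seq_along(tr))
        g[pos >= GenomicRanges::start(tr)[i] &
            pos <= GenomicRanges::end(tr)[i]] <- tr$gamma[i]
    }
    parts[[k]] <- simulateTreeSites(tree, n, gamma = g, donor = dr[1],
                                    recipient = dr[2], tMig = model@tMig,
                                    chrom = chroms[k], positions = pos)
  }
  gm <- GenotypeMatrix(tree$tip.label,
                       unlist(lapply(parts, chromosomes)),
                       unlist(lapply(parts, positions)),
                       do.call(rbind, lapply(parts, genotypes)))
  list(genotypes = gm, truth = tracts)
}

#' Simulate a single-species genome with planted low-heterozygosity tracts
#'
#' Each site is heterozygous (genotype 1) with probability `baseHet`
#' outside the planted tracts and `hetFactor * baseHet` inside them,
#' emulating runs of homozygosity from inbreeding.
#'
#' @param chromLengths named integer vector of chromosome lengths (bp).
#' @param baseHet background per-site heterozygosity in [0, 1].
#' @param rohTracts `GRanges` of planted low-het tracts (non-overlapping),
#'   or NULL.
#' @param seed RNG seed.
#' @param siteDensity callable sites per bp (default 0.01).
#' @param hetFactor in-tract heterozygosity multiplier (default 0.02).
#' @param species sample label.
#' @return list with `genotypes` (single-species [GenotypeMatrix-class])
#'   and `truth` (the tract `GRanges`).
#' @export
simulateHetGenome <- function(chromLengths, baseHet, rohTracts = NULL,
                              seed = NULL, siteDensity = 0.01,
                              hetFactor = 0.02, species = "S1") {
  if (baseHet < 0 || baseHet > 1) stop("baseHet must lie in [0, 1]")
  .setSeed(seed)
  if (!is.null(rohTracts) &&
      length(GenomicRanges::reduce(rohTracts)) != length(rohTracts))
    stop("overlapping tracts")
  chroms <- names(chromLengths)
  if (is.null(chroms)) chroms <- paste0("chr", seq_along(chromLengths))
  allChrom <- character(0); allPos <- integer(0); allGeno <- integer(0)
  for (k in seq_along(chromLengths)) {
    L <- chromLengths[[k]]
    n <- max(2L, round(L * siteDensity))
    pos <- sort(sample.int(L, n))
    p <- rep(baseHet, n)
    if (!is.null(rohTracts)) {
      tr <- rohTracts[as.character(GenomicRanges::seqnames(rohTracts)) ==
                        chroms[k]]
      for (i in seq_along(tr))
        p[pos >= GenomicRanges::start(tr)[i] &
            pos <= GenomicRanges::end(tr)[i]] <- hetFactor * baseHet
    }
    allChrom <- c(allChrom, rep(chroms[k], n))
    allPos <- c(allPos, pos)
    allGeno <- c(allGeno, rbinom(n, 1L, p))
  }
  gm <- GenotypeMatrix(species, allChrom, allPos,
                       matrix(allGeno, ncol = 1))
  list(genotypes = gm, truth = rohTracts)
}

.bumpField <- function(xm, ym, cx, cy, radius, nBumps) {
  f <- matrix(0, nrow(xm), ncol(xm))
  for (b in seq_len(nBumps)) {
    a <- runif(1, -1, 1)
    th <- runif(1, 0, 2 * pi)
    r0 <- radius * sqrt(runif(1))
    bx <- cx + r0 * cos(th)
    by <- cy + r0 * sin(th)
    w <- runif(1, radius / 6, radius / 3)
    f <- f + a * exp(-((xm - bx)^2 + (ym - by)^2) / (2 * w^2))
  }
  f
}

#' Simulate an island elevation raster plus smooth bioclim-like layers
#'
#' The island is a radial cone (peak at the grid centre, shoreline at
#' `radius`) with optional smooth Gaussian-bump noise on land; sea cells
#' are nodata.  Environmental layers are smooth seeded fields (linear
#' gradients plus bumps) defined on the same land mask.
#'
#' @param gridSize cells per side (square grid).
#' @param cellsize cell size in coordinate units.
#' @param peak cone peak elevation; @param radius island radius in
#'   coordinate units (default 0.4 of the grid width).
#' @param noiseAmp elevation noise amplitude (0 gives the analytic cone).
#' @param nBumps Gaussian bumps per smooth field.
#' @param nVars number of bioclim-like layers.
#' @param seed RNG seed.
#' @return list with `elevation` (an [EnvRaster-class]) and `bioclim`
#'   (named list Bio1..BioN of [EnvRaster-class]).
#' @export
simulateIslandRasters <- function(gridSize = 120, cellsize = 1, peak = 1000,
                                  radius = NULL, noiseAmp = 0, nBumps = 8,
                                  nVars = 4, seed = NULL) {
  .setSeed(seed)
  if (is.null(radius)) radius <- 0.4 * gridSize * cellsize
  n <- gridSize
  xc <- (seq_len(n) - 0.5) * cellsize            # col -> x
  yc <- (n - seq_len(n) + 0.5) * cellsize        # row -> y (row 1 = north)
  xm <- matrix(xc, n, n, byrow = TRUE)
  ym <- matrix(yc, n, n)
  cx <- n * cellsize / 2
  cy <- n * cellsize / 2
  dist <- sqrt((xm - cx)^2 + (ym - cy)^2)
  land <- dist < radius
  elev <- peak * (1 - dist / radius)
  if (noiseAmp > 0)
    elev <- elev + noiseAmp * .bumpField(xm, ym, cx, cy, radius, nBumps)
  elev[land] <- pmax(elev[land], 0.01)           # noise never sinks land
  elev[!land] <- NA
  elevation <- EnvRaster(elev, cellsize = cellsize)
  bioclim <- vector("list", nVars)
  names(bioclim) <- paste0("Bio", seq_len(nVars))
  for (v in seq_len(nVars)) {
    a <- runif(3, -1, 1)
    f <- a[1] * (xm - cx) / radius + a[2] * (ym - cy) / radius +
      a[3] * .bumpField(xm, ym, cx, cy, radius, nBumps)
    f <- 10 + 5 * f
    f[!land] <- NA
    bioclim[[v]] <- EnvRaster(f, cellsize = cellsize)
  }
  list(elevation = elevation, bioclim = bioclim)
}

#' Sample occurrences uniformly from the cells satisfying true niche ranges
#'
#' @param rasters named list of [EnvRaster-class] layers (shared grid).
#' @param trueRanges named list `variable = c(min, max)`; every listed
#'   variable must name a raster.
#' @param n number of points; sampled uniformly among suitable cells (with
#'   replacement), placed at cell centres.
#' @param seed RNG seed; @param species label for the output.
#' @return data.frame (species, lon, lat).
#' @export
sampleOccurrences <- function(rasters, trueRanges, n, seed = NULL,
                              species = "sp1") {
  .setSeed(seed)
  miss <- setdiff(names(trueRanges), names(rasters))
  if (length(miss)) stop("no raster for variable(s): ",
                         paste(miss, collapse = ", "))
  r1 <- rasters[[names(trueRanges)[1]]]
  ok <- matrix(TRUE, r1@nrows, r1@ncols)
  for (v in names(trueRanges)) {
    vals <- rasters[[v]]@values
    rng <- trueRanges[[v]]
    ok <- ok & !is.na(vals) & vals >= rng[1] & vals <= rng[2]
  }
  idx <- which(ok)
  if (length(idx) == 0) stop("no cell satisfies all true ranges")
  pick <- idx[sample.int(length(idx), n, replace = TRUE)]
  row <- (pick - 1) %% r1@nrows + 1
  col <- (pick - 1) %/% r1@nrows + 1
  data.frame(species = species,
             lon = r1@xll + (col - 0.5) * r1@cellsize,
             lat = r1@yll + (r1@nrows - row + 0.5) * r1@cellsize)
}
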