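## Central S4 containers.  Tables that are naturally flat (valence tables,
## ROH summaries, area curves) stay plain data.frames; GRanges is used for
## genomic segments.

#' GenotypeMatrix: per-site diploid genotypes for one sample per species
#'
#' Sites are biallelic SNPs; `geno[i, s]` is the count of derived/ALT alleles
#' (0, 1, 2 or `NA` for missing) carried by the single diploid individual of
#' species `s` at site `i`.  Positions are 1-based and strictly increasing
#' within a chromosome.
#'
#' @slot species character, ordered species/sample labels.
#' @slot chrom character, per-site chromosome id.
#' @slot pos integer, per-site 1-based coordinate (bp).
#' @slot geno integer matrix, sites x species, values in 0/1/2/NA.
#' @export
setClass("GenotypeMatrix",
  representation(species = "character", chrom = "character",
                 pos = "integer", geno = "matrix"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  if (nrow(object@geno) != length(object@pos))
    msg <- c(msg, "nrow(geno) must equal length(pos)")
  if (ncol(object@geno) != length(object@species))
    msg <- c(msg, "ncol(geno) must equal length(species)")
  if (length(object@chrom) != length(object@pos))
    msg <- c(msg, "chrom and pos lengths differ")
  if (anyDuplicated(object@species))
    msg <- c(msg, "duplicated species labels")
  g <- object@geno
  if (!all(g[!is.na(g)] %in% 0:2))
    msg <- c(msg, "genotype values must be 0, 1, 2 or NA")
  if (length(object@pos) > 1L) {
    bad <- tapply(object@pos, object@chrom,
                  function(p) any(diff(p) <= 0))
    if (any(unlist(bad)))
      msg <- c(msg, "pos must be strictly increasing within each chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param species character vector of species labels (one diploid sample each).
#' @param chrom per-site chromosome ids.
#' @param pos per-site 1-based positions.
#' @param geno integer matrix (sites x species) of derived/ALT allele counts.
#' @return A [GenotypeMatrix-class] object.
#' @examples
#' gm <- GenotypeMatrix(c("P1", "P2"), rep("chr1", 3), c(10L, 20L, 30L),
#'                      matrix(c(0L, 1L, 2L, 0L, 0L, 2L), ncol = 2))
#' nSites(gm)
#' @export
GenotypeMatrix <- function(species, chrom, pos, geno) {
  storage.mode(geno) <- "integer"
  colnames(geno) <- species
  new("GenotypeMatrix", species = as.character(species),
      chrom = as.character(chrom), pos = as.integer(pos), geno = geno)
}

#' EnvRaster: a regular gridded environmental layer (ESRI ASCII model)
#'
#' `values` is stored in map orientation: row 1 is the northernmost row,
#' column 1 the westernmost column.  Missing (nodata) cells are `NA`
#' internally and written out as the `nodata` sentinel.
#'
#' @slot nrows,ncols grid dimensions.
#' @slot xll,yll lower-left corner coordinates.
#' @slot cellsize grid spacing (> 0).
#' @slot nodata sentinel written for missing cells.
#' @slot values numeric matrix, nrows x ncols, NA for nodata.
#' @export
setClass("EnvRaster",
  representation(nrows = "integer", ncols = "integer", xll = "numeric",
                 yll = "numeric", cellsize = "numeric", nodata = "numeric",
                 values = "matrix"))

setValidity("EnvRaster", function(object) {
  msg <- character()
  if (object@cellsize <= 0) msg <- c(msg, "cellsize must be > 0")
  if (nrow(object@values) != object@nrows ||
      ncol(object@values) != object@ncols)
    msg <- c(msg, "values shape does not match declared nrows/ncols")
  if (length(msg)) msg else TRUE
})

#' Construct an EnvRaster
#'
#' @param values numeric matrix (row 1 = north), NA for nodata.
#' @param xll,yll lower-left corner; @param cellsize cell size;
#' @param nodata nodata sentinel used on write.
#' @return An [EnvRaster-class].
#' @export
EnvRaster <- function(values, xll = 0, yll = 0, cellsize = 1,
                      nodata = -9999) {
  new("EnvRaster", nrows = nrow(values), ncols = ncol(values),
      xll = as.numeric(xll), yll = as.numeric(yll),
      cellsize = as.numeric(cellsize), nodata = as.numeric(nodata),
      values = values)
}

#' QuartetModel: coalescent model for a species quartet (((P1,P2),P3),O)
#'
#' Split times are in coalescent units before present: `t1` (P1-P2), `t2`
#' ((P1,P2)-P3), `t3` (ingroup-outgroup).  With probability `gamma` per site
#' the recipient lineage traces back into the donor population at time
#' `tMig` (< t1), i.e. forwards-in-time gene flow donor -> recipient.
#'
#' @slot t1,t2,t3 split times, 0 < tMig < t1 < t2 < t3.
#' @slot gamma per-site introgression probability in [0, 1].
#' @slot tMig introgression time.
#' @slot direction `"P3->P2"` (default) or `"P2->P3"` (donor -> recipient).
#' @export
setClass("QuartetModel",
  representation(t1 = "numeric", t2 = "numeric", t3 = "numeric",
                 gamma = "numeric", tMig = "numeric", direction = "character"))

setValidity("QuartetModel", function(object) {
  msg <- character()
  if (!(object@tMig > 0 && object@tMig < object@t1 &&
        object@t1 < object@t2 && object@t2 < object@t3))
    msg <- c(msg, "need 0 < tMig < t1 < t2 < t3")
  if (object@gamma < 0 || object@gamma > 1)
    msg <- c(msg, "gamma must lie in [0, 1]")
  if (!object@direction %in% c("P3->P2", "P2->P3"))
    msg <- c(msg, "direction must be 'P3->P2' or 'P2->P3'")
  if (length(msg)) msg else TRUE
})

#' Construct a QuartetModel
#'
#' @param t1,t2,t3 split times in coalescent units (t1 < t2 < t3).
#' @param gamma per-site introgression probability.
#' @param tMig introgression time (< t1).
#' @param direction donor -> recipient, `"P3->P2"` or `"P2->P3"`.
#' @return A [QuartetModel-class].
#' @export
quartetModel <- function(t1 = 1, t2 = 2, t3 = 4, gamma = 0,
                         tMig = 0.1, direction = "P3->P2") {
  new("QuartetModel", t1 = t1, t2 = t2, t3 = t3, gamma = gamma,
      tMig = tMig, direction = direction)
}

#' SitePatternCounts: frequency-weighted ABBA/BABA sums with block partials
#'
#' @slot abba,baba total weighted sums.
#' @slot nUsed number of informative sites used.
#' @slot blockAbba,blockBaba per-block partial sums (equal-site blocks).
#' @slot quartet the (P1, P2, P3, O) labels.
#' @export
setClass("SitePatternCounts",
  representation(abba = "numeric", baba = "numeric", nUsed = "integer",
                 blockAbba = "numeric", blockBaba = "numeric",
                 quartet = "character"))

setValidity("SitePatternCounts", function(object) {
  msg <- character()
  if (object@abba < 0 || object@baba < 0)
    msg <- c(msg, "abba and baba must be non-negative")
  if (length(object@blockAbba) != length(object@blockBaba))
    msg <- c(msg, "block partial vectors differ in length")
  if (abs(sum(object@blockAbba) - object@abba) > 1e-8 * (1 + object@abba) ||
      abs(sum(object@blockBaba) - object@baba) > 1e-8 * (1 + object@baba))
    msg <- c(msg, "block partials must sum to the totals")
  if (length(msg)) msg else TRUE
})

#' WindowScan: non-overlapping tiling-window D scan
#'
#' `windows` holds one row per window with columns `chrom`, `start` (0-based),
#' `end` (half-open), `nUsed`, `abba`, `baba`, `d` and `masked` (windows with
#' fewer than `minSites` informative sites carry no D).
#'
#' @slot w window size in bp.
#' @slot quartet the (P1, P2, P3, O) labels.
#' @slot minSites mask threshold.
#' @slot windows data.frame as described above.
#' @export
setClass("WindowScan",
  representation(w = "numeric", quartet = "character", minSites = "numeric",
                 windows = "data.frame"))

#' IntervalResult: interval-length timing analysis of significant windows
#'
#' Gaps are bp between adjacent significant windows on the same chromosome
#' (0 when adjacent); the control is the same computation over windows drawn
#' uniformly without replacement from the unmasked windows.  The one-sided
#' Mann-Whitney U test asks whether significant-set gaps are smaller than
#' control gaps.
#'
#' @slot gaps,controlGaps observed and control gap lengths (bp).
#' @slot U Mann-Whitney U statistic; @slot p one-sided p value.
#' @slot nControl number of control windows; @slot seed RNG seed used.
#' @export
setClass("IntervalResult",
  representation(gaps = "numeric", controlGaps = "numeric", U = "numeric",
                 p = "numeric", nControl = "integer", seed = "integer"))

#' CompetitionConfig: coupled logistic competition model configuration
#'
#' The model is dX/dt = a X (1 - (X+Y)/m), dY/dt = b Y (1 - (X+Y)/n).
#' The run is divided into three stages: growth, a perturbation stage whose
#' entry multiplies Y by `rho` instantly and X by `rho` after a delay
#' `delay`, and recovery.
#'
#' @slot a,b intrinsic growth rates (per unit model time).
#' @slot m,n equilibrium (carrying-capacity) population sizes.
#' @slot X0,Y0 initial sizes.
#' @slot tStage1End,tStage2End,tFinal stage boundaries (increasing).
#' @slot rho perturbation factor in (0, 1].
#' @slot delay delay of the species-1 perturbation (model-time units).
#' @slot dt integration step; @slot integrator "rk4" or "euler".
#' @export
setClass("CompetitionConfig",
  representation(a = "numeric", b = "numeric", m = "numeric", n = "numeric",
                 X0 = "numeric", Y0 = "numeric", tStage1End = "numeric",
                 tStage2End = "numeric", tFinal = "numeric", rho = "numeric",
                 delay = "numeric", dt = "numeric", integrator = "character"))

setValidity("CompetitionConfig", function(object) {
  msg <- character()
  if (object@a <= 0 || object@b <= 0) msg <- c(msg, "a and b must be > 0")
  if (object@m <= 0 || object@n <= 0) msg <- c(msg, "m and n must be > 0")
  if (object@X0 < 0 || object@Y0 < 0) msg <- c(msg, "X0 and Y0 must be >= 0")
  if (!(object@rho > 0 && object@rho <= 1))
    msg <- c(msg, "rho must lie in (0, 1]")
  if (!(0 < object@tStage1End && object@tStage1End < object@tStage2End &&
        object@tStage2End < object@tFinal))
    msg <- c(msg, "stage boundaries must satisfy 0 < t1 < t2 < tFinal")
  if (object@delay < 0) msg <- c(msg, "delay must be >= 0")
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  stages <- c(object@tStage1End, object@tStage2End - object@tStage1End,
              object@tFinal - object@tStage2End)
  if (object@dt >= min(stages))
    msg <- c(msg, "dt must be smaller than the shortest stage")
  if (!object@integrator %in% c("rk4", "euler"))
    msg <- c(msg, "integrator must be 'rk4' or 'euler'")
  if (length(msg)) msg else TRUE
})

#' Construct a CompetitionConfig
#'
#' Defaults produce the qualitative regime of interest: shared growth to a
#' joint carrying capacity, an asynchronous two-species crash during stage 2
#' (species 2 first, species 1 after `delay` = 5e5 time units), and recovery.
#'
#' @param a,b growth rates; @param m,n carrying capacities;
#' @param X0,Y0 initial sizes; @param tStage1End,tStage2End,tFinal stage
#'   boundaries; @param rho perturbation factor; @param delay species-1
#'   perturbation delay; @param dt step; @param integrator "rk4" or "euler".
#' @return A [CompetitionConfig-class].
#' @export
competitionConfig <- function(a = 2e-6, b = 2e-6, m = 1e6, n = 1e6,
                              X0 = 1e4, Y0 = 1e4, tStage1End = 3e6,
                              tStage2End = 6e6, tFinal = 1e7, rho = 0.1,
                              delay = 5e5, dt = 500, integrator = "rk4") {
  new("CompetitionConfig", a = a, b = b, m = m, n = n, X0 = X0, Y0 = Y0,
      tStage1End = tStage1End, tStage2End = tStage2End, tFinal = tFinal,
      rho = rho, delay = delay, dt = dt, integrator = integrator)
}

#' Trajectory: time series of the two competing populations
#'
#' @slot time uniform time grid (spacing dt); at an event time the stored
#'   value is the post-perturbation one.
#' @slot X,Y population sizes.
#' @slot events data.frame (time, species, factor) of applied perturbations.
#' @export
setClass("Trajectory",
  representation(time = "numeric", X = "numeric", Y = "numeric",
                 events = "data.frame"))

setValidity("Trajectory", function(object) {
  msg <- character()
  if (length(object@X) != length(object@time) ||
      length(object@Y) != length(object@time))
    msg <- c(msg, "time, X, Y lengths differ")
  if (any(object@X < 0) || any(object@Y < 0))
    msg <- c(msg, "populations must be non-negative")
  if (length(msg)) msg else TRUE
})

#' NicheSpace: PCA environmental niche space fitted on background cells
#'
#' @slot center,scale standardisation parameters of the input variables.
#' @slot rotation loading matrix (variables x PCs).
#' @slot sdev PC standard deviations.
#' @slot bgScores background (land-cell) scores on PC1/PC2.
#' @slot extent c(xmin, xmax, ymin, ymax) of the background scores.
#' @export
setClass("NicheSpace",
  representation(center = "numeric", scale = "numeric", rotation = "matrix",
                 sdev = "numeric", bgScores = "matrix", extent = "numeric"))

#' DensityGrid: normalised occurrence density in niche space
#'
#' @slot z R x R density matrix summing to 1.
#' @slot x,y grid cell-centre coordinates (PC1, PC2).
#' @slot bandwidth the two KDE bandwidths used.
#' @export
setClass("DensityGrid",
  representation(z = "matrix", x = "numeric", y = "numeric",
                 bandwidth = "numeric"))

setValidity("DensityGrid", function(object) {
  msg <- character()
  if (any(object@z < 0)) msg <- c(msg, "density must be non-negative")
  if (abs(sum(object@z) - 1) > 1e-9)
    msg <- c(msg, "density must sum to 1 (within 1e-9)")
  if (length(msg)) msg else TRUE
})
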