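## Accessors and show methods.

#' @rdname GenotypeMatrix-class
#' @export
setMethod("speciesNames", "GenotypeMatrix", function(x) x@species)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("nSites", "GenotypeMatrix", function(x) length(x@pos))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("genotypes", "GenotypeMatrix", function(x) x@geno)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("positions", "GenotypeMatrix", function(x) x@pos)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("chromosomes", "GenotypeMatrix", function(x) x@chrom)

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", length(object@pos), "biallelic sites x",
      length(object@species), "species\n")
  cat("  species:", paste(object@species, collapse = ", "), "\n")
  cat("  chromosomes:", paste(unique(object@chrom), collapse = ", "), "\n")
  nmiss <- sum(is.na(object@geno))
  cat("  missing genotypes:", nmiss, "\n")
})

#' @rdname EnvRaster-class
#' @export
setMethod("rasterValues", "EnvRaster", function(x) x@values)

#' @rdname EnvRaster-class
#' @export
setMethod("cellSize", "EnvRaster", function(x) x@cellsize)

setMethod("show", "EnvRaster", function(object) {
  v <- object@values
  cat(sprintf("EnvRaster: %d rows x %d cols, cellsize %g, origin (%g, %g)\n",
              object@nrows, object@ncols, object@cellsize, object@xll,
              object@yll))
  cat(sprintf("  data cells: %d (nodata: %d); range: [%g, %g]\n",
              sum(!is.na(v)), sum(is.na(v)),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
})

setMethod("show", "QuartetModel", function(object) {
  cat(sprintf(
    "QuartetModel (((P1,P2):%g,P3):%g,O):%g; gamma = %g at t = %g (%s)\n",
    object@t1, object@t2, object@t3, object@gamma, object@tMig,
    object@direction))
})

setMethod("show", "SitePatternCounts", function(object) {
  cat(sprintf("SitePatternCounts [%s]\n",
              paste(object@quartet, collapse = ", ")))
  cat(sprintf("  ABBA = %.4f, BABA = %.4f over %d informative sites (%d blocks)\n",
              object@abba, object@baba, object@nUsed,
              length(object@blockAbba)))
})

#' @rdname WindowScan-class
#' @export
setMethod("scanWindows", "WindowScan", function(x) x@windows)

setMethod("show", "WindowScan", function(object) {
  w <- object@windows
  cat(sprintf("WindowScan: %d windows of %g bp [%s], minSites = %g\n",
              nrow(w), object@w, paste(object@quartet, collapse = ","),
              object@minSites))
  cat(sprintf("  unmasked: %d; mean D (unmasked): %.4f\n",
              sum(!w$masked), mean(w$d[!w$masked])))
})

#' @rdname IntervalResult-class
#' @export
setMethod("gapLengths", "IntervalResult", function(x) x@gaps)

#' @rdname IntervalResult-class
#' @export
setMethod("controlGapLengths", "IntervalResult", function(x) x@controlGaps)

setMethod("show", "IntervalResult", function(object) {
  cat(sprintf(
    "IntervalResult: %d gaps vs %d control gaps; U = %g, one-sided p = %.4g\n",
    length(object@gaps), length(object@controlGaps), object@U, object@p))
})

setMethod("show", "CompetitionConfig", function(object) {
  cat(sprintf("CompetitionConfig: a=%g b=%g m=%g n=%g X0=%g Y0=%g\n",
              object@a, object@b, object@m, object@n, object@X0, object@Y0))
  cat(sprintf("  stages: [0,%g] [%g,%g] [%g,%g]; rho=%g delay=%g dt=%g (%s)\n",
              object@tStage1End, object@tStage1End, object@tStage2End,
              object@tStage2End, object@tFinal, object@rho, object@delay,
              object@dt, object@integrator))
})

#' @rdname Trajectory-class
#' @export
setMethod("trajectory", "Trajectory", function(x)
  data.frame(t = x@time, X = x@X, Y = x@Y))

#' @rdname Trajectory-class
#' @export
setMethod("perturbationEvents", "Trajectory", function(x) x@events)

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d points on [%g, %g]\n", length(object@time),
              object@time[1], object@time[length(object@time)]))
  cat(sprintf("  final X = %.4g, Y = %.4g; %d perturbation events\n",
              object@X[length(object@X)], object@Y[length(object@Y)],
              nrow(object@events)))
})

setMethod("show", "NicheSpace", function(object) {
  ev <- object@sdev^2 / sum(object@sdev^2)
  cat(sprintf(
    "NicheSpace: %d variables, %d background cells; PC1/PC2 variance %.1f%%/%.1f%%\n",
    nrow(object@rotation), nrow(object@bgScores), 100 * ev[1], 100 * ev[2]))
})

#' @rdname DensityGrid-class
#' @export
setMethod("densityValues", "DensityGrid", function(x) x@z)

setMethod("show", "DensityGrid", function(object) {
  cat(sprintf("DensityGrid: %d x %d, bandwidth (%.3g, %.3g), sum(z) = %g\n",
              nrow(object@z), ncol(object@z), object@bandwidth[1],
              object@bandwidth[2], sum(object@z)))
})
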