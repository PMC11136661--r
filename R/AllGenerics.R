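#' @rdname GenotypeMatrix-class
#' @param object,x a package object.
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))

#' @rdname EnvRaster-class
#' @export
setGeneric("rasterValues", function(x) standardGeneric("rasterValues"))

#' @rdname EnvRaster-class
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' @rdname WindowScan-class
#' @export
setGeneric("scanWindows", function(x) standardGeneric("scanWindows"))

#' @rdname DensityGrid-class
#' @export
setGeneric("densityValues", function(x) standardGeneric("densityValues"))

#' @rdname IntervalResult-class
#' @export
setGeneric("gapLengths", function(x) standardGeneric("gapLengths"))

#' @rdname IntervalResult-class
#' @export
setGeneric("controlGapLengths",
           function(x) standardGeneric("controlGapLengths"))

#' @rdname Trajectory-class
#' @export
setGeneric("trajectory", function(x) standardGeneric("trajectory"))

#' @rdname Trajectory-class
#' @export
setGeneric("perturbationEvents",
           function(x) standardGeneric("perturbationEvents"))
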