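## Readers/writers for the standard formats the pipeline touches, plus the
## GATK-style hard filter.  Coordinate conventions: VCF positions are
## 1-based; all window/tract/ROH output is BED-style 0-based half-open, and
## the conversion happens exactly once, at the I/O boundary.

#' Read biallelic SNP genotypes from a VCF
#'
#' Keeps biallelic SNP records only; multiallelic records and indels are
#' skipped and counted.  Genotypes are encoded as the count of ALT alleles
#' (0/1/2); missing GT becomes `NA`.
#'
#' @param path VCF file (plain text or gzipped).
#' @param speciesMap named character vector mapping VCF sample names to
#'   species labels, e.g. `c(sampleA = "P1")`.  `NULL` uses the sample names
#'   themselves.
#' @return A [GenotypeMatrix-class]; attribute `nSkipped` counts the
#'   non-biallelic-SNP records dropped.
#' @export
readVcfGenotypes <- function(path, speciesMap = NULL) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & !grepl(",", alt) & nchar(ref) == 1L &
    nchar(alt) == 1L & ref != alt
  nskip <- sum(!keep)
  if (nskip > 0)
    message("readVcfGenotypes: skipped ", nskip,
            " non-biallelic-SNP record(s)")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, names(gt)))
  samples <- colnames(gt)
  if (is.null(speciesMap)) speciesMap <- setNames(samples, samples)
  missing <- setdiff(names(speciesMap), samples)
  if (length(missing))
    stop("sample(s) in speciesMap absent from VCF header: ",
         paste(missing, collapse = ", "))
  gt <- gt[keep, names(speciesMap), drop = FALSE]
  geno <- matrix(NA_integer_, nrow(gt), ncol(gt))
  for (j in seq_len(ncol(gt))) {
    g <- gt[, j]
    al <- strsplit(gsub("\\|", "/", g), "/", fixed = TRUE)
    geno[, j] <- vapply(al, function(a) {
      a <- suppressWarnings(as.integer(a))
      if (length(a) == 0 || anyNA(a)) NA_integer_ else sum(a)
    }, integer(1))
  }
  gm <- GenotypeMatrix(unname(speciesMap), fix[keep, "CHROM"],
                       as.integer(fix[keep, "POS"]), geno)
  attr(gm, "nSkipped") <- nskip
  gm
}

#' Write a GenotypeMatrix as a minimal VCF
#'
#' Emits a valid VCF 4.2 file with GT-only genotype columns (REF = A,
#' ALT = T placeholders); the inverse of [readVcfGenotypes()] for objects
#' produced by the package's simulators.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeVcfGenotypes <- function(gm, path) {
  stopifnot(is(gm, "GenotypeMatrix"))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  g <- gm@geno
  gtxt <- matrix("./.", nrow(g), ncol(g))
  ok <- !is.na(g)
  gtxt[ok] <- gt_code[as.character(g[ok])]
  header <- c("##fileformat=VCFv4.2",
              "##source=baobab",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", gm@species), collapse = "\t"))
  body <- paste(gm@chrom, gm@pos, ".", "A", "T", ".", "PASS", ".", "GT",
                sep = "\t")
  body <- paste(body, apply(gtxt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Default GATK-style hard-filter thresholds
#'
#' A record fails when any annotation violates its bound: QD < 2.0,
#' QUAL < 30.0, SOR > 3.0, FS > 60.0, MQ < 40.0, MQRankSum < -12.5,
#' ReadPosRankSum < -8.0.  Inequalities are strict, so boundary values pass.
#'
#' @return Named list of thresholds.
#' @export
hardFilterDefaults <- function() {
  list(QD = 2.0, QUAL = 30.0, SOR = 3.0, FS = 60.0, MQ = 40.0,
       MQRankSum = -12.5, ReadPosRankSum = -8.0)
}

#' Apply GATK-style hard filters to a table of variant annotations
#'
#' A record is removed iff any of QD < 2.0, QUAL < 30.0, SOR > 3.0,
#' FS > 60.0, MQ < 40.0, MQRankSum < -12.5 or ReadPosRankSum < -8.0 (all
#' configurable).  An annotation missing from a record (NA or absent
#' column) passes that criterion, GATK-style, and is counted in the
#' `nMissing` attribute.
#'
#' @param records data.frame carrying any subset of the annotation columns.
#' @param thresholds named list as from [hardFilterDefaults()].
#' @return The retained rows; attributes `nRemoved` (count) and `nMissing`
#'   (per-annotation missing counts).
#' @export
applyHardFilters <- function(records, thresholds = hardFilterDefaults()) {
  stopifnot(is.data.frame(records))
  lower <- c("QD", "QUAL", "MQ", "MQRankSum", "ReadPosRankSum")
  fail <- rep(FALSE, nrow(records))
  nmissing <- integer(0)
  for (ann in names(thresholds)) {
    if (!ann %in% names(records)) {
      nmissing[ann] <- nrow(records)
      next
    }
    x <- records[[ann]]
    nmissing[ann] <- sum(is.na(x))
    bad <- if (ann %in% lower) x < thresholds[[ann]] else x > thresholds[[ann]]
    bad[is.na(bad)] <- FALSE
    fail <- fail | bad
  }
  if (any(nmissing > 0))
    message("applyHardFilters: missing annotations treated as passing: ",
            paste(sprintf("%s=%d", names(nmissing)[nmissing > 0],
                          nmissing[nmissing > 0]), collapse = ", "))
  out <- records[!fail, , drop = FALSE]
  attr(out, "nRemoved") <- sum(fail)
  attr(out, "nMissing") <- nmissing
  out
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` file with NCOLS/NROWS/XLLCORNER/YLLCORNER/CELLSIZE/
#'   NODATA_VALUE header.
#' @return An [EnvRaster-class]; nodata cells become `NA`.
#' @export
readAsc <- function(path) {
  if (!file.exists(path)) stop("cannot read raster: ", path)
  lines <- readLines(path, n = 6)
  kv <- strsplit(trimws(lines), "\\s+")
  keys <- toupper(vapply(kv, `[`, "", 1))
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  need <- c("NCOLS", "NROWS", "XLLCORNER", "YLLCORNER", "CELLSIZE",
            "NODATA_VALUE")
  if (!all(need %in% keys) || anyNA(vals[need]))
    stop("malformed ESRI ASCII header in ", path)
  ncols <- as.integer(vals["NCOLS"])
  nrows <- as.integer(vals["NROWS"])
  vv <- scan(path, skip = 6, quiet = TRUE)
  if (length(vv) != nrows * ncols)
    stop(sprintf("raster body has %d values; header declares %d x %d",
                 length(vv), nrows, ncols))
  m <- matrix(vv, nrow = nrows, ncol = ncols, byrow = TRUE)
  m[m == vals["NODATA_VALUE"]] <- NA
  EnvRaster(m, xll = vals["XLLCORNER"], yll = vals["YLLCORNER"],
            cellsize = vals["CELLSIZE"], nodata = vals["NODATA_VALUE"])
}

#' Write an EnvRaster as an ESRI ASCII grid
#'
#' Values are written with enough digits to round-trip through [readAsc()]
#' to at least 6 significant digits.
#'
#' @param raster an [EnvRaster-class]; @param path output file.
#' @return `path`, invisibly.
#' @export
writeAsc <- function(raster, path) {
  stopifnot(is(raster, "EnvRaster"))
  m <- raster@values
  m[is.na(m)] <- raster@nodata
  hdr <- c(paste("NCOLS", raster@ncols), paste("NROWS", raster@nrows),
           paste("XLLCORNER", format(raster@xll, digits = 12)),
           paste("YLLCORNER", format(raster@yll, digits = 12)),
           paste("CELLSIZE", format(raster@cellsize, digits = 12)),
           paste("NODATA_VALUE", format(raster@nodata, digits = 12)))
  rows <- apply(m, 1, function(r)
    paste(format(r, digits = 10, trim = TRUE, scientific = FALSE),
          collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read species occurrence records
#'
#' @param path CSV with header `species,lon,lat`.
#' @return data.frame with those columns.
#' @export
readOccurrences <- function(path) {
  occ <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  need <- c("species", "lon", "lat")
  if (!all(need %in% names(occ)))
    stop("occurrence CSV must have columns species,lon,lat")
  occ[, need]
}

#' Write species occurrence records
#'
#' @param occ data.frame with columns species, lon, lat; @param path file.
#' @return `path`, invisibly.
#' @export
writeOccurrences <- function(occ, path) {
  write.table(occ[, c("species", "lon", "lat")], path, sep = ",",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sea-level curve
#'
#' @param path two-column CSV (header `age,level_m`): age before present and
#'   sea level relative to present (m).
#' @return data.frame with columns age, level_m.
#' @export
readSeaLevelCurve <- function(path) {
  sl <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  if (ncol(sl) < 2) stop("sea-level CSV needs two columns (age, level_m)")
  names(sl)[1:2] <- c("age", "level_m")
  sl[, 1:2]
}

#' Export genomic segments as BED
#'
#' GRanges (1-based closed) are converted to BED 0-based half-open by
#' rtracklayer at this boundary.
#'
#' @param gr a `GRanges`; an mcols column `name` is carried into BED col 4.
#' @param path output `.bed` file.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Import a BED file as GRanges
#'
#' @param path `.bed` file.
#' @return A `GRanges` (1-based closed coordinates).
#' @export
readBed <- function(path) {
  rtracklayer::import(path, format = "BED")
}
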