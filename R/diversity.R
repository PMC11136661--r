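## Windowed heterozygosity (GWH) profiling and ROH calling with the
## long/intermediate/short length classification.
##
## Per-window observed heterozygosity is the fraction of callable
## (genotyped) sites that are heterozygous; at low theta this converges to
## the per-site population-genetic theta, so the genome-wide ratio
## sum(n_het)/sum(n_callable) is the GWH estimate.  ROH are maximal runs of
## consecutive windows whose heterozygosity falls at or below an explicit
## threshold (default: a quarter of the genome-wide median window
## heterozygosity).

#' Windowed heterozygosity profile
#'
#' Tiling windows [k*w, (k+1)*w) (0-based half-open).  `het` is
#' n_het / n_callable; windows with no callable site get `NaN`, not 0.
#'
#' @param gm a [GenotypeMatrix-class]; @param species which sample;
#' @param w window size in bp (default 100,000).
#' @return data.frame: chrom, start, end, nCallable, nHet, het.
#' @export
windowedHet <- function(gm, species, w = 1e5) {
  stopifnot(is(gm, "GenotypeMatrix"), w > 0)
  if (!species %in% gm@species) stop("species not in matrix: ", species)
  g <- gm@geno[, species]
  out <- list()
  for (ch in unique(gm@chrom)) {
    sel <- gm@chrom == ch
    pos <- gm@pos[sel]
    gch <- g[sel]
    nwin <- ceiling(max(pos) / w)
    widx <- (pos - 1) %/% w + 1
    callable <- !is.na(gch)
    nCall <- tabulate(widx[callable], nbins = nwin)
    nHet <- tabulate(widx[callable & gch == 1L], nbins = nwin)
    out[[ch]] <- data.frame(chrom = ch, start = (seq_len(nwin) - 1) * w,
                            end = seq_len(nwin) * w, nCallable = nCall,
                            nHet = nHet,
                            het = ifelse(nCall > 0, nHet / nCall, NaN))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Per-chromosome and genome-wide heterozygosity (theta-hat)
#'
#' Ratios of summed heterozygous to summed callable sites, the GWH
#' estimate per chromosome and over the whole genome.
#'
#' @param profile output of [windowedHet()].
#' @return list with `perChromosome` (data.frame chrom, nCallable, nHet,
#'   theta) and `genome` (the genome-wide ratio).
#' @export
genomeHet <- function(profile) {
  if (all(profile$nCallable == 0)) stop("no callable windows")
  agg <- do.call(rbind, lapply(split(profile, profile$chrom), function(p)
    data.frame(chrom = p$chrom[1], nCallable = sum(p$nCallable),
               nHet = sum(p$nHet))))
  agg$theta <- agg$nHet / agg$nCallable
  rownames(agg) <- NULL
  list(perChromosome = agg,
       genome = sum(agg$nHet) / sum(agg$nCallable))
}

.rohClass <- function(len) {
  ifelse(len > 2e6, "long", ifelse(len >= 5e5, "intermediate", "short"))
}

#' Call runs of homozygosity from a heterozygosity profile
#'
#' Maximal runs of consecutive windows with het <= `hetThreshold` become
#' candidate segments; runs on the same chromosome separated by at most
#' `mergeGap` intervening windows are merged; merged runs shorter than
#' `minLen` bp are dropped.  Length classes: short < 500 kb <=
#' intermediate <= 2 Mb < long (long ROH indicate recent inbreeding).
#'
#' @param profile output of [windowedHet()].
#' @param hetThreshold het cutoff; default 0.25 x the genome-wide median
#'   window het (computed over callable windows).
#' @param minLen minimum segment length in bp (default 300,000).
#' @param mergeGap maximum number of intervening windows bridged when
#'   merging runs (default 1).
#' @return `GRanges` (1-based) with mcols `lengthBp` and `class`; the
#'   threshold used is in the `hetThreshold` attribute.
#' @export
callRoh <- function(profile, hetThreshold = NULL, minLen = 3e5,
                    mergeGap = 1) {
  stopifnot(minLen > 0, mergeGap >= 0)
  callable <- profile$nCallable > 0
  if (is.null(hetThreshold)) {
    if (!any(callable)) stop("no callable windows")
    hetThreshold <- 0.25 * median(profile$het[callable])
  }
  segs <- list()
  for (ch in unique(profile$chrom)) {
    p <- profile[profile$chrom == ch, , drop = FALSE]
    p <- p[order(p$start), , drop = FALSE]
    low <- p$nCallable > 0 & p$het <= hetThreshold
    r <- rle(low)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- data.frame(from = starts[r$values], to = ends[r$values])
    if (nrow(runs) == 0) next
    ## merge runs separated by <= mergeGap windows
    merged <- runs[1, , drop = FALSE]
    if (nrow(runs) > 1) {
      for (i in 2:nrow(runs)) {
        if (runs$from[i] - merged$to[nrow(merged)] - 1 <= mergeGap)
          merged$to[nrow(merged)] <- runs$to[i]
        else merged <- rbind(merged, runs[i, ])
      }
    }
    segs[[ch]] <- data.frame(chrom = ch,
                             start = p$start[merged$from],
                             end = p$end[merged$to])
  }
  if (length(segs) == 0) {
    out <- GenomicRanges::GRanges()
  } else {
    df <- do.call(rbind, segs)
    df <- df[df$end - df$start >= minLen, , drop = FALSE]
    out <- GenomicRanges::GRanges(df$chrom,
                                  IRanges(df$start + 1, df$end))
    out$lengthBp <- df$end - df$start
    out$class <- .rohClass(out$lengthBp)
  }
  attr(out, "hetThreshold") <- hetThreshold
  out
}

#' Summarise ROH segments
#'
#' @param segments `GRanges` from [callRoh()].
#' @param topN size of the longest-segment listing (default 100).
#' @return list with `byClass` (data.frame class, n, totalLengthBp over
#'   short/intermediate/long), `totalLengthBp`, and `topLongest` (the
#'   length-sorted top-N listing as a data.frame).
#' @export
rohSummary <- function(segments, topN = 100) {
  classes <- c("short", "intermediate", "long")
  if (length(segments) == 0) {
    byClass <- data.frame(class = classes, n = 0L, totalLengthBp = 0)
    return(list(byClass = byClass, totalLengthBp = 0,
                topLongest = data.frame(chrom = character(0),
                                        start = numeric(0),
                                        end = numeric(0),
                                        lengthBp = numeric(0),
                                        class = character(0))))
  }
  len <- segments$lengthBp
  cls <- factor(segments$class, levels = classes)
  byClass <- data.frame(class = classes,
                        n = as.integer(table(cls)),
                        totalLengthBp = as.numeric(tapply(len, cls, sum,
                                                          default = 0)))
  ord <- order(-len)
  top <- head(ord, topN)
  topLongest <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(segments))[top],
    start = GenomicRanges::start(segments)[top] - 1,
    end = GenomicRanges::end(segments)[top],
    lengthBp = len[top], class = as.character(cls)[top])
  list(byClass = byClass, totalLengthBp = sum(len), topLongest = topLongest)
}
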