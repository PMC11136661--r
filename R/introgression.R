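## Quartet site-pattern statistics (Patterson's D, block-jackknife Z,
## f4-admixture ratio), tree-wide f-branch mapping, the 100-kb tiling
## window scan, and the interval-length timing analysis.
##
## Frequency-weighted ABBA/BABA convention: with per-species derived-allele
## frequencies p1..p4,
##   ABBA = sum (1-p1) p2 p3 (1-p4),   BABA = sum p1 (1-p2) p3 (1-p4).
## With one diploid individual per species p is geno/2, in {0, 0.5, 1}.
## Polarization: the derived allele is the allele absent from the outgroup;
## sites where the single outgroup individual is heterozygous cannot be
## polarized and are skipped, and sites where the outgroup carries the ALT
## allele homozygously are flipped.

## Polarized derived-allele frequencies for the requested species.
## Returns a matrix of p values (sites kept x species) for sites where all
## requested species are genotyped and the outgroup is homozygous.
.polarizedFreqs <- function(gm, species, outgroup) {
  idx <- match(unique(c(species, outgroup)), gm@species)
  if (anyNA(idx))
    stop("species not in matrix: ",
         paste(unique(c(species, outgroup))[is.na(idx)], collapse = ", "))
  g <- gm@geno[, unique(c(species, outgroup)), drop = FALSE]
  keep <- rowSums(is.na(g)) == 0L & g[, outgroup] != 1L
  g <- g[keep, , drop = FALSE]
  p <- g / 2
  flip <- p[, outgroup] > 0.5
  p[flip, ] <- 1 - p[flip, , drop = FALSE]
  list(p = p, keep = keep)
}

.abbaBabaWeights <- function(p, quartet) {
  p1 <- p[, quartet[1]]; p2 <- p[, quartet[2]]
  p3 <- p[, quartet[3]]; p4 <- p[, quartet[4]]
  list(abba = (1 - p1) * p2 * p3 * (1 - p4),
       baba = p1 * (1 - p2) * p3 * (1 - p4))
}

## Contiguous equal-count block assignment (1..nBlocks) for n sites.
.blockIds <- function(n, nBlocks) {
  if (n == 0) return(integer(0))
  as.integer(((seq_len(n) - 1) * nBlocks) %/% n) + 1L
}

#' Frequency-weighted ABBA/BABA sums with block partials
#'
#' Sites with any missing genotype in the quartet, or with a heterozygous
#' outgroup, are skipped; sites where the outgroup is homozygous for the
#' ALT allele are repolarized so that derived means "absent from the
#' outgroup".  Blocks are contiguous with equal numbers of used sites.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param quartet character(4): (P1, P2, P3, O), four distinct species.
#' @param nBlocks number of jackknife blocks (default 20).
#' @return A [SitePatternCounts-class].
#' @export
sitePatternSums <- function(gm, quartet, nBlocks = 20) {
  stopifnot(is(gm, "GenotypeMatrix"))
  if (length(quartet) != 4 || anyDuplicated(quartet))
    stop("quartet must name four distinct species")
  pf <- .polarizedFreqs(gm, quartet, quartet[4])
  wts <- .abbaBabaWeights(pf$p, quartet)
  n <- nrow(pf$p)
  blocks <- .blockIds(n, nBlocks)
  ba <- vapply(seq_len(nBlocks), function(b) sum(wts$abba[blocks == b]),
               numeric(1))
  bb <- vapply(seq_len(nBlocks), function(b) sum(wts$baba[blocks == b]),
               numeric(1))
  new("SitePatternCounts", abba = sum(wts$abba), baba = sum(wts$baba),
      nUsed = n, blockAbba = ba, blockBaba = bb, quartet = quartet)
}

#' Patterson's D statistic
#'
#' D = (ABBA - BABA) / (ABBA + BABA).  When ABBA + BABA = 0 the test is
#' unperformable and `NaN` is returned.
#'
#' @param abba,baba weighted sums, or a [SitePatternCounts-class] as the
#'   first argument.
#' @return D in [-1, 1], or NaN.
#' @export
pattersonD <- function(abba, baba = NULL) {
  if (is(abba, "SitePatternCounts")) {
    baba <- abba@baba
    abba <- abba@abba
  }
  tot <- abba + baba
  ifelse(tot > 0, (abba - baba) / tot, NaN)
}

#' Block-jackknife Z score for Patterson's D
#'
#' Delete-one-block jackknife over contiguous equal-site blocks:
#' se^2 = (g-1)/g * sum_j (D_(j) - mean(D_(j)))^2 with D_(j) the statistic
#' recomputed without block j; Z = D / se.  Degenerate cases (fewer than 2
#' non-empty blocks, or se = 0) give Z = NaN.
#'
#' @param counts a [SitePatternCounts-class].
#' @return list(d, se, z, nBlocks).
#' @export
blockJackknife <- function(counts) {
  stopifnot(is(counts, "SitePatternCounts"))
  A <- counts@abba; B <- counts@baba
  d <- pattersonD(A, B)
  nonEmpty <- (counts@blockAbba + counts@blockBaba) > 0
  g <- length(counts@blockAbba)
  if (sum(nonEmpty) < 2 || !is.finite(d))
    return(list(d = d, se = NaN, z = NaN, nBlocks = g))
  dj <- (A - counts@blockAbba - (B - counts@blockBaba)) /
    (A - counts@blockAbba + (B - counts@blockBaba))
  se <- sqrt((g - 1) / g * sum((dj - mean(dj))^2))
  z <- if (se > 0) d / se else NaN
  list(d = d, se = se, z = z, nBlocks = g)
}

#' Full D-statistic summary for one quartet
#'
#' @param gm a [GenotypeMatrix-class]; @param quartet (P1, P2, P3, O);
#' @param nBlocks jackknife blocks.
#' @return one-row data.frame: P1, P2, P3, O, nUsed, abba, baba, d, se, z,
#'   f4ratio.
#' @export
dStatistic <- function(gm, quartet, nBlocks = 20) {
  cnt <- sitePatternSums(gm, quartet, nBlocks)
  jk <- blockJackknife(cnt)
  f4 <- f4AdmixtureRatio(gm, quartet)
  data.frame(P1 = quartet[1], P2 = quartet[2], P3 = quartet[3],
             O = quartet[4], nUsed = cnt@nUsed, abba = cnt@abba,
             baba = cnt@baba, d = jk$d, se = jk$se, z = jk$z, f4ratio = f4)
}

#' f4-admixture ratio
#'
#' The admixture-fraction estimator f = num(P1,P2,P3,O) / num(P1,P3,P3,O),
#' where num = ABBA - BABA under the frequency weighting and the donor P3
#' is substituted for the recipient in the denominator (the
#' homozygous-proxy estimator).  Both sums use the same polarized sites
#' (all four species genotyped, outgroup homozygous).
#'
#' @param gm a [GenotypeMatrix-class]; @param quartet (P1, P2, P3, O).
#' @return The estimate, or NaN when the denominator is not positive.
#' @export
f4AdmixtureRatio <- function(gm, quartet) {
  stopifnot(length(quartet) == 4)
  pf <- .polarizedFreqs(gm, quartet[1:3], quartet[4])
  p <- pf$p
  p1 <- p[, quartet[1]]; p2 <- p[, quartet[2]]; p3 <- p[, quartet[3]]
  p4 <- p[, quartet[4]]
  num <- sum((1 - p4) * p3 * (p2 - p1))
  den <- sum((1 - p4) * p3 * (p3 - p1))
  if (!(den > 0)) {
    message("f4AdmixtureRatio: non-positive denominator; unperformable")
    return(NaN)
  }
  num / den
}

## Internal-branch lettering: LETTERS in post-order over internal nodes
## (root excluded); leaf branches are named by their tip label.
.branchTable <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  po <- ape::reorder.phylo(tree, "postorder")
  internal <- unique(po$edge[, 1][po$edge[, 1] != root])
  ## child nodes of all edges = every branch
  childNodes <- tree$edge[, 2]
  ids <- character(max(tree$edge))
  ids[seq_len(ntip)] <- tree$tip.label
  ids[internal] <- LETTERS[seq_along(internal)]
  data.frame(node = childNodes, id = ids[childNodes],
             stringsAsFactors = FALSE)
}

.tipsUnder <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  tree$tip.label[unlist(phangorn::Descendants(tree, node, "tips"))]
}

#' f-branch matrix: mapping gene-flow signal onto species-tree branches
#'
#' For each branch b of the ingroup tree and each candidate donor species C
#' not descended from b,
#' f_b(C) = median over B in descendants(b) of
#'          [ min over A in descendants(sister(b)), A != C, of f4(A,B,C,O) ].
#' Cells with no valid (A, B) combination are NaN (unperformable); negative
#' estimates are floored at 0 and counted in the `nFloored` attribute.
#'
#' @param tree rooted `phylo` whose tips are species of `gm` (the outgroup
#'   tip, if present, is dropped before branch enumeration).
#' @param gm a [GenotypeMatrix-class].
#' @param outgroup outgroup species label.
#' @return numeric matrix (branches x donor species) with branch ids as
#'   row names: tip labels for terminal branches, letters A, B, C, ... in
#'   post-order for internal branches.
#' @export
fBranch <- function(tree, gm, outgroup) {
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  if (outgroup %in% tree$tip.label)
    tree <- ape::drop.tip(tree, outgroup)
  if (!all(tree$tip.label %in% gm@species))
    stop("tree leaves must be species of the genotype matrix")
  tips <- tree$tip.label
  br <- .branchTable(tree)
  ntip <- length(tips)
  root <- ntip + 1L
  fb <- matrix(NaN, nrow(br), length(tips),
               dimnames = list(br$id, tips))
  nFloored <- 0L
  f4cache <- new.env(hash = TRUE)
  f4 <- function(A, B, C) {
    key <- paste(A, B, C, sep = "|")
    if (!is.null(f4cache[[key]])) return(f4cache[[key]])
    val <- f4AdmixtureRatio(gm, c(A, B, C, outgroup))
    f4cache[[key]] <- val
    val
  }
  for (i in seq_len(nrow(br))) {
    v <- br$node[i]
    parent <- tree$edge[tree$edge[, 2] == v, 1]
    sibs <- setdiff(tree$edge[tree$edge[, 1] == parent, 2], v)
    descB <- .tipsUnder(tree, v)
    descA <- unlist(lapply(sibs, .tipsUnder, tree = tree))
    for (C in setdiff(tips, descB)) {
      aSet <- setdiff(descA, C)
      if (length(aSet) == 0) next
      medB <- vapply(descB, function(B) {
        vals <- vapply(aSet, function(A) f4(A, B, C), numeric(1))
        vals <- vals[is.finite(vals)]
        if (length(vals) == 0) NaN else min(vals)
      }, numeric(1))
      medB <- medB[is.finite(medB)]
      if (length(medB) == 0) next
      val <- median(medB)
      if (is.finite(val) && val < 0) {
        nFloored <- nFloored + 1L
        val <- 0
      }
      fb[i, C] <- val
    }
  }
  if (nFloored > 0)
    message("fBranch: ", nFloored, " negative cell(s) floored at 0")
  attr(fb, "nFloored") <- nFloored
  fb
}

#' Tiling-window D scan
#'
#' Non-overlapping windows [k*w, (k+1)*w) (0-based half-open) tile each
#' chromosome; D is computed from each window's own weighted sums.  Windows
#' with fewer than `minSites` used sites (or an empty ABBA+BABA sum) are
#' masked and carry no D.
#'
#' @param gm a [GenotypeMatrix-class]; @param quartet (P1, P2, P3, O);
#' @param w window size in bp (default 100,000); @param minSites mask
#'   threshold (default 20 used sites).
#' @return A [WindowScan-class].
#' @export
windowScan <- function(gm, quartet, w = 1e5, minSites = 20) {
  stopifnot(is(gm, "GenotypeMatrix"), w > 0)
  pf <- .polarizedFreqs(gm, quartet, quartet[4])
  wts <- .abbaBabaWeights(pf$p, quartet)
  chrom <- gm@chrom[pf$keep]
  pos <- gm@pos[pf$keep]
  out <- list()
  for (ch in unique(gm@chrom)) {
    maxPos <- max(gm@pos[gm@chrom == ch])
    nwin <- ceiling(maxPos / w)
    sel <- chrom == ch
    widx <- (pos[sel] - 1) %/% w + 1        # 1-based window index
    abba <- baba <- numeric(nwin)
    sa <- rowsum(cbind(wts$abba[sel], wts$baba[sel]), widx)
    got <- as.integer(rownames(sa))
    abba[got] <- sa[, 1]
    baba[got] <- sa[, 2]
    nUsed <- tabulate(widx, nbins = nwin)
    d <- ifelse(abba + baba > 0, (abba - baba) / (abba + baba), NaN)
    masked <- nUsed < minSites | !is.finite(d)
    d[masked] <- NA_real_
    out[[ch]] <- data.frame(chrom = ch,
                            start = (seq_len(nwin) - 1) * w,
                            end = seq_len(nwin) * w,
                            nUsed = nUsed, abba = abba, baba = baba,
                            d = d, masked = masked)
  }
  new("WindowScan", w = w, quartet = quartet, minSites = minSites,
      windows = do.call(rbind, c(out, list(make.row.names = FALSE))))
}

#' Select top-|D| significant windows
#'
#' Ranks unmasked windows by |D| descending and selects the top
#' ceiling(q * N); ties at the cutoff are broken by (chrom, start)
#' ascending.  The selected set is split by the sign of D.
#'
#' @param scan a [WindowScan-class]; @param q significance quantile in
#'   (0, 1), e.g. 0.01, 0.05 or 0.10.
#' @return list(positive, negative, selected, q): data.frames of windows.
#' @export
classifyWindows <- function(scan, q) {
  stopifnot(is(scan, "WindowScan"), q > 0, q < 1)
  wdf <- scan@windows[!scan@windows$masked, , drop = FALSE]
  if (nrow(wdf) == 0) stop("all windows are masked")
  k <- ceiling(q * nrow(wdf))
  ord <- order(-abs(wdf$d), wdf$chrom, wdf$start)
  sel <- wdf[ord[seq_len(k)], , drop = FALSE]
  list(positive = sel[sel$d > 0, , drop = FALSE],
       negative = sel[sel$d < 0, , drop = FALSE],
       selected = sel, q = q)
}

.gapsBetween <- function(windows) {
  gaps <- numeric(0)
  for (ch in unique(windows$chrom)) {
    wch <- windows[windows$chrom == ch, , drop = FALSE]
    if (nrow(wch) < 2) next
    wch <- wch[order(wch$start), , drop = FALSE]
    gaps <- c(gaps, wch$start[-1] - wch$end[-nrow(wch)])
  }
  gaps
}

#' Interval-length timing analysis of significant windows
#'
#' Computes the bp gap between adjacent significant windows on each
#' chromosome (0 when the windows are adjacent), draws `nControl` windows
#' uniformly without replacement from the unmasked windows as a control,
#' computes control gaps identically, and applies a one-sided
#' Mann-Whitney/Wilcoxon rank-sum test (normal approximation with
#' continuity and tie correction) of whether significant-set gaps are
#' smaller than control gaps.  Small and zero gaps indicate large, recent
#' introgressed regions.
#'
#' @param scan a [WindowScan-class].
#' @param significant data.frame of significant windows (a class from
#'   [classifyWindows()]); at least 2 windows.
#' @param nControl number of control windows (default 100).
#' @param seed RNG seed for control sampling.
#' @return An [IntervalResult-class].
#' @export
intervalAnalysis <- function(scan, significant, nControl = 100,
                             seed = NULL) {
  stopifnot(is(scan, "WindowScan"))
  if (nrow(significant) < 2)
    stop("unperformable: fewer than 2 significant windows")
  .setSeed(seed)
  unmasked <- scan@windows[!scan@windows$masked, , drop = FALSE]
  if (nControl > nrow(unmasked)) {
    message("intervalAnalysis: only ", nrow(unmasked),
            " unmasked windows; using all as control")
    nControl <- nrow(unmasked)
  }
  ctrl <- unmasked[sample.int(nrow(unmasked), nControl), , drop = FALSE]
  gaps <- .gapsBetween(significant)
  controlGaps <- .gapsBetween(ctrl)
  if (length(gaps) == 0 || length(controlGaps) == 0)
    stop("unperformable: no within-chromosome gaps")
  wt <- suppressWarnings(wilcox.test(gaps, controlGaps,
                                     alternative = "less", exact = FALSE,
                                     correct = TRUE))
  new("IntervalResult", gaps = gaps, controlGaps = controlGaps,
      U = unname(wt$statistic), p = wt$p.value,
      nControl = as.integer(nControl),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}
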