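## Independent oracles and small fixture builders used across the suite.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

## Brute-force per-site ABBA/BABA computation: explicit loop, explicit
## polarization, independent of the vectorised implementation.
bruteSitePattern <- function(gm, quartet) {
  g <- genotypes(gm)[, quartet, drop = FALSE]
  abba <- 0; baba <- 0; n <- 0L
  for (i in seq_len(nrow(g))) {
    r <- unname(g[i, ])
    if (any(is.na(r))) next
    if (r[4] == 1L) next                 # outgroup heterozygous: skip
    p <- r / 2
    if (p[4] > 0.5) p <- 1 - p           # repolarize
    abba <- abba + (1 - p[1]) * p[2] * p[3] * (1 - p[4])
    baba <- baba + p[1] * (1 - p[2]) * p[3] * (1 - p[4])
    n <- n + 1L
  }
  list(abba = abba, baba = baba, n = n)
}

## Independent pure-R quartet coalescent (no gene flow): explicit
## case-by-case epochs, used to cross-check the compiled site simulator.
## Returns an n x 4 0/1 matrix of derived states (P1, P2, P3, O).
oracleQuartetSites <- function(n, t1, t2, t3) {
  out <- matrix(0L, n, 4)
  for (s in seq_len(n)) {
    eMask <- vector("list", 8); eLen <- numeric(8); ne <- 0L
    add <- function(mask, len) {
      ne <<- ne + 1L
      eMask[[ne]] <<- mask
      eLen[ne] <<- len
    }
    ## epoch [t1, t2): only P1 and P2 share a population
    w <- rexp(1)
    if (t1 + w < t2) {
      tc <- t1 + w
      add(1L, tc); add(2L, tc)
      lin <- list(list(m = c(1L, 2L), b = tc), list(m = 3L, b = 0))
    } else {
      lin <- list(list(m = 1L, b = 0), list(m = 2L, b = 0),
                  list(m = 3L, b = 0))
    }
    t <- t2
    ## epoch [t2, t3): everyone but the outgroup
    repeat {
      k <- length(lin)
      if (k == 1) break
      w <- rexp(1, k * (k - 1) / 2)
      if (t + w >= t3) break
      t <- t + w
      pr <- sample.int(k, 2)
      for (j in pr) add(lin[[j]]$m, t - lin[[j]]$b)
      merged <- list(m = c(lin[[pr[1]]]$m, lin[[pr[2]]]$m), b = t)
      lin <- c(lin[-pr], list(merged))
    }
    ## root population from t3, with the outgroup
    t <- t3
    lin <- c(lin, list(list(m = 4L, b = 0)))   # O sampled at the present
    repeat {
      k <- length(lin)
      if (k == 1) break
      t <- t + rexp(1, k * (k - 1) / 2)
      pr <- sample.int(k, 2)
      for (j in pr) add(lin[[j]]$m, t - lin[[j]]$b)
      merged <- list(m = c(lin[[pr[1]]]$m, lin[[pr[2]]]$m), b = t)
      lin <- c(lin[-pr], list(merged))
    }
    u <- runif(1, 0, sum(eLen[seq_len(ne)]))
    acc <- 0
    for (e in seq_len(ne)) {
      acc <- acc + eLen[e]
      if (u <= acc) { out[s, eMask[[e]]] <- 1L; break }
    }
  }
  out
}

## classify a 0/1 derived row into a site-pattern label for (P1,P2,P3,O)
patternLabel <- function(der) {
  key <- paste(der, collapse = "")
  switch(key, "1100" = "BBAA", "0110" = "ABBA", "1010" = "BABA", "other")
}

toyGenotypeMatrix <- function(geno, species = c("P1", "P2", "P3", "O"),
                              chrom = NULL, pos = NULL) {
  geno <- matrix(as.integer(geno), ncol = length(species))
  if (is.null(chrom)) chrom <- rep("chr1", nrow(geno))
  if (is.null(pos)) pos <- seq_len(nrow(geno))
  GenotypeMatrix(species, chrom, pos, geno)
}

## hand-rolled tiny VCF text fixture
writeToyVcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=QD,Number=1,Type=Float,Description="qd">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", "s1", "s2"), collapse = "\t"),
    "chr1\t100\t.\tA\tT\t50\tPASS\tQD=20\tGT\t0/1\t1/1",
    "chr1\t200\t.\tG\tA,C\t50\tPASS\tQD=20\tGT\t0/1\t0/2",
    "chr1\t300\t.\tC\tG\t50\tPASS\tQD=20\tGT\t./.\t0|0")
  writeLines(lines, path)
  path
}

## a WindowScan built directly from a windows table (for ranking tests)
toyScan <- function(d, masked = rep(FALSE, length(d)), w = 1e5,
                    chrom = rep("chr1", length(d))) {
  n <- length(d)
  start <- (ave(seq_len(n), chrom, FUN = seq_along) - 1) * w
  df <- data.frame(chrom = chrom, start = start, end = start + w,
                   nUsed = rep(100L, n), abba = rep(1, n), baba = rep(1, n),
                   d = d, masked = masked)
  df$d[masked] <- NA_real_
  new("WindowScan", w = w, quartet = c("P1", "P2", "P3", "O"),
      minSites = 20, windows = df)
}
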