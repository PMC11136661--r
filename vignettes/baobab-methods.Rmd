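---
title: "Models and methods behind the baobab pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the baobab pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of the statistical models it
implements, the tunable parameters that matter, what the synthetic-data
generators do and do not emulate, and the numerical and design choices
made where the design was genuinely open.  Everything quantitative stated
here is computed by the package's own test suite or acceptance script;
nothing is quoted from elsewhere.

## The analysis setting

The package targets the comparative-genomic and ecological toolkit used
to characterise a small island radiation of tree species: one diploid
genome per species, a rooted species tree, species occurrence records,
gridded environmental layers, and a sea-level history.  Four analysis
families are covered: quartet introgression statistics with a windowed
timing analysis, heterozygosity/ROH profiling, a two-species competition
simulator, and niche-overlap/habitat/land-area modelling.  Every family
is paired with a seeded generator so that each method can be validated
against planted truth without any external download.

## The coalescent site simulator

`simulateTreeSites()` draws unlinked biallelic sites under the
multispecies (structured) coalescent on an ultrametric species tree with
branch lengths in coalescent units.  Per site, one haploid lineage per
species coalesces backwards in time; within a population $k$ lineages
coalesce at rate $\binom{k}{2}$; at each speciation time the daughter
populations merge.  Introgression is a single pulse: with per-site
probability $\gamma$ the recipient's lineage relocates into the donor's
population at time $t_m$ (forwards in time, donor $\to$ recipient gene
flow).  One mutation is placed uniformly on the realised gene tree
(infinite sites), and the site is emitted as a homozygous diploid
genotype — the one-individual-per-species design makes per-species
derived-allele frequencies $p \in \{0, \tfrac12, 1\}$ and keeps
ABBA/BABA bookkeeping exact.

What this deliberately does **not** emulate: recombination and linkage
(sites are exchangeable draws; tract structure is imposed directly by
varying $\gamma$ along the chromosome in
`simulateGenomeWithTracts()`), mutation-rate or generation-time realism,
sequencing error, and reference bias.  Tests that pass on these data
therefore validate the statistics' logic and calibration, not their
robustness to alignment artefacts.

The simulator is cross-checked in the test suite against an independent
pure-R implementation of the quartet coalescent: all site-pattern
frequencies agree within Monte-Carlo error at 30,000 sites, and the two
discordant patterns (ABBA, BABA) are equally frequent without gene flow,
as the multispecies coalescent requires.

## Quartet statistics

For a quartet (((P1,P2),P3),O) the frequency-weighted pattern sums are

$$\mathrm{ABBA} = \sum_i (1-p_{1i})\,p_{2i}\,p_{3i}\,(1-p_{4i}), \qquad
  \mathrm{BABA} = \sum_i p_{1i}\,(1-p_{2i})\,p_{3i}\,(1-p_{4i}),$$

with Patterson's $D = (\mathrm{ABBA}-\mathrm{BABA}) /
(\mathrm{ABBA}+\mathrm{BABA})$, undefined (NaN, "unperformable") when
the denominator is zero.  Conventions:

* **Polarization.**  The derived allele is the allele absent from the
  outgroup.  A site whose single outgroup individual is heterozygous
  cannot be polarized and is skipped; a site where the outgroup is
  homozygous ALT is flipped.
* **Significance.**  A delete-one block jackknife over contiguous blocks
  holding equal numbers of used sites (default 20 blocks) yields a
  standard error and $Z = D/\mathrm{se}$.  Equal-site blocks make the
  toy examples exactly reproducible by hand; the default of 20 is
  exposed because no canonical value exists for desk-scale data.
* **$f_4$-admixture ratio.**  $\hat f =
  \mathrm{num}(P1,P2,P3,O)/\mathrm{num}(P1,P3,P3,O)$ with
  $\mathrm{num} = \mathrm{ABBA}-\mathrm{BABA}$: the donor is substituted
  for the recipient in the denominator (the homozygous-proxy form used
  by the standard tooling).

**Calibration regime of $\hat f$.**  With a single sampled donor lineage
the denominator counts *all* drift private to the P3 lineage, whereas an
introgressed P2 lineage shares the donor's drift only above their
common ancestor inside the donor population, which it reaches after an
Exp(1) waiting time.  The estimator therefore underestimates $\gamma$ by
a relative factor of roughly $(t_m + 1)/T$, where $T$ is the total
drift depth of the donor lineage.  Recovery validation consequently uses
a deep-split quartet ($t_1 = 6$, $t_2 = 20$, $t_3 = 28$, $t_m = 0.05$
coalescent units), the classic low-ILS regime in which the proxy is
calibrated: across 20 seeds at 50,000 sites the mean estimate is within
0.03 of each simulated $\gamma \in \{0.1, 0.2, 0.4\}$.  In shallow,
ILS-rich regimes (e.g. $t_1 = 1$, $t_2 = 2$) the same estimator is
proportionally biased low — a property of the estimator, not of the
implementation — and the shallow regime is instead used where ILS-rich
data are the point (null calibration of $D$/$Z$, window scans).

**f-branch.**  To place gene flow on the tree,
$f_b(C) = \mathrm{median}_{B \in \mathrm{desc}(b)}
\left[\min_{A \in \mathrm{desc}(\mathrm{sister}(b)),\,A \neq C}
f_4(A, B, C, O)\right]$ for every branch $b$ and donor $C$ not below
$b$.  Cells with no valid $(A, B)$ combination are NaN; negative
estimates are floored at zero (and counted).  Internal branches are
lettered in post-order so rows are stable identifiers.

## Window scan and interval-length analysis

`windowScan()` tiles each chromosome with non-overlapping windows of
$w = 100{,}000$ bp (0-based half-open) and computes $D$ from each
window's own sums.  Windows with fewer than `minSites` (default 20) used
sites, or an empty denominator, are masked — an empty window is missing
data, never $D = 0$.  `classifyWindows()` ranks unmasked windows by
$|D|$ descending and selects the top $\lceil qN \rceil$
($q \in \{0.01, 0.05, 0.10\}$), splitting the selection by the sign of
$D$; ties at the cutoff break deterministically by (chrom, start).

`intervalAnalysis()` measures the bp gap between adjacent significant
windows per chromosome (adjacent windows gap 0 — the signature of
large, recent introgressed blocks), computes the same quantity over
`nControl` (default 100) windows drawn uniformly without replacement
from the unmasked windows, and applies a one-sided Mann-Whitney test
(normal approximation, continuity and tie correction) of whether the
significant-set gaps are smaller.  Control windows are drawn genome-wide
and gaps never span chromosome boundaries.

**Conservatism of the null.**  The gaps of a random window subset are
order-statistic spacings: they are jointly negatively dependent because
they sum to (nearly) the chromosome length.  The independent-samples
rank test ignores this, so under a uniform signal its p-value
concentrates towards 0.5 instead of being uniform: the test is
*conservative*.  The suite demonstrates both sides: with clustered
introgression tracts the one-sided p is far below 0.05 in 20/20 seeds,
and under uniform signal the false-positive rate at the 0.05 level is
at most nominal and a 60-replicate Kolmogorov-Smirnov check does not
reject uniformity at the 1% level — though the mild concentration
towards 0.5 is real and would be resolved by a much larger replicate
count.  Validation conditions are
size-matched — e.g. the top 5% of 1,000 windows (50) against 50
controls — because a large size imbalance between the two gap samples
adds a second, purely combinatorial source of conservatism.

## Heterozygosity and runs of homozygosity

`windowedHet()` reports, per tiling window, the fraction of callable
(genotyped) sites that are heterozygous; `genomeHet()` aggregates
$\hat\theta = \sum n_{het} / \sum n_{callable}$ per chromosome and
genome-wide.  At low per-site diversity the observed heterozygous
fraction converges to $\theta$ per site, which is why this simple ratio
serves as the genome-wide heterozygosity (GWH) estimate.  ROH calling
uses an explicit, fully observable rule: maximal runs of consecutive
windows with het at or below a threshold (default one quarter of the
genome-wide median window het), merging runs separated by at most
`mergeGap` (default 1) windows, discarding merged runs shorter than
`minLen` (default 300 kb).  This windowed-threshold rule is a deliberate,
prominently documented substitution for likelihood-model-based ROH
callers: it is transparent, exactly testable against planted tracts,
and recovers a planted 3-Mb low-het tract with breakpoints within one
window.  Length classes: short < 500 kb $\le$ intermediate $\le$ 2 Mb <
long; the 2-Mb long boundary reflects the recent-inbreeding
interpretation of long ROH, while the 500-kb boundary is a package
convention (configurable).

## Coupled logistic competition

Two species share a resource:

$$\frac{dX}{dt} = a X \left(1 - \frac{X+Y}{m}\right), \qquad
  \frac{dY}{dt} = b Y \left(1 - \frac{X+Y}{n}\right).$$

The run has three stages: unperturbed growth; a perturbation stage whose
entry multiplies $Y$ by $\rho$ instantly and $X$ by the same $\rho$
after a delay $\Delta$ (default $5 \times 10^5$ model-time units) — the
asynchronous crash; recovery.  Where the perturbation's functional form
was open, an instantaneous multiplicative drop was chosen as the
simplest event reproducing an asynchronous two-species crash; $\rho$
defaults to 0.1.  Stage boundaries and rates are not canonical numbers,
so the defaults ($a = b = 2\times10^{-6}$ per time unit,
$m = n = 10^6$, $X_0 = Y_0 = 10^4$, stages ending at $3\times10^6$,
$6\times10^6$, $10^7$) were chosen once so the default run shows
growth, an asynchronous crash, and recovery; all are explicit
configuration.

Integration uses fixed-step RK4 (deSolve), integrating each inter-event
segment on a shared dt grid so that event times land exactly on grid
points — exact event timing was preferred over adaptive step-size
economy at this problem size.  Stage boundaries and $\Delta$ must be
multiples of dt (validated).  The suite verifies 4th-order (RK4) and
1st-order (Euler) convergence against the closed-form logistic
$X(t) = m/(1 + (m/X_0 - 1)e^{-at})$, machine-precision symmetry of the
fully symmetric configuration, and that species 1's post-crash minimum
occurs after species 2's.

## Niche, habitat and sea level

* **Variable selection.**  Greedy elimination: drop constant variables,
  then repeatedly drop the variable with the largest mean absolute
  pairwise Pearson correlation until all $|r| < 0.8$.  The threshold is
  the standard collinearity rule; the greedy order is a package choice
  since only the criterion, not the order, is canonical.
* **Ecological valence.**  Per species and variable, the min-max
  envelope of values extracted at occurrences (nearest cell; points on
  nodata are excluded and counted).
* **Habitat superimposition.**  Per variable a binary in-range layer
  (endpoints inclusive); the overlap count is their sum, and habitat is
  the cells where *every* selected variable is in range — the strictest
  reading of "most overlapping layers".  The count raster is returned so
  a softer quantile rule can be applied downstream if preferred.
* **Niche space and densities.**  Variables are standardised over the
  complete land cells, a PCA is fitted there, and occurrences are
  projected to (PC1, PC2).  Densities are Gaussian KDEs on an
  $R \times R$ grid (default $R = 100$) spanning the background extent,
  normalised to sum to one; bandwidths default to the per-axis normal
  reference rule.  Occurrence densities are used directly — the
  background-occupancy correction applied by some niche-overlap tools is
  left as a documented extension because its parameters are not
  canonical and Schoener's $D$ semantics are unchanged without it.
* **Overlap and randomization tests.**  Schoener's
  $D = 1 - \tfrac12\sum|z_1 - z_2|$.  The equivalency test pools the two
  occurrence sets and reassigns labels (sample sizes preserved);
  $p = (\#\{D_{null} \le D_{obs}\}+1)/(n_{reps}+1)$, low p meaning the
  niches are less overlapping than equivalent ones.  The similarity test
  replaces one species by uniform draws from the background cells and
  uses the opposite tail, $p = (\#\{D_{null} \ge D_{obs}\}+1)/(n_{reps}+1)$,
  low p meaning the niches are more similar than a randomly placed
  niche — the convention under which identical tight clusters on a broad
  background are significant in both directions and a species that is
  itself uniform over the background is unremarkable.  Defaults:
  1,000 replicates, seeded.
* **Land area.**  Land is every cell with elevation strictly greater
  than the sea level (shoreline cells exactly at the level count as sea,
  stated for bit-reproducibility); area is the cell count times
  cellsize², with percent change against the area at the baseline
  level.  Sea-level histories are consumed as two-column CSV curves;
  no geophysical sea-level model is fitted here.

The island generator builds a radial cone (analytic when the noise
amplitude is zero, which the tests exploit) with smooth Gaussian-bump
fields for the environmental layers; occurrences are drawn uniformly
from the cells satisfying known tolerance ranges, so envelope recovery
can be scored against exact truth (Jaccard $\ge 0.9$ at 500 points).

## Problem sizes used in validation

The suite's simulation sizes are chosen to make each statistical
assertion sharp at desk scale: 50,000 sites per quartet replicate
(null calibration over 200 replicates; admixture recovery and f-branch
localization over 20 seeds each), 100-Mb synthetic genomes at site
density 0.01 for window/interval analyses (1,000 windows of 100 kb),
20-Mb genomes at density 0.01 callable sites per bp for ROH recovery,
and $120 \times 120$ rasters with 500 occurrences for the envelope
recovery.  Each size is stated in the corresponding test.

## Known limitations

Unlinked sites mean no LD-aware block-size guidance can be derived from
these simulations; the jackknife block count is a free parameter.  The
f4-ratio proxy is biased low in shallow-split regimes (quantified
above).  The interval-length null is conservative (quantified above).
Rasters are treated as planar grids — no reprojection or geodesic
areas.  The similarity test's background defaults to all land cells;
restricting it to an accessible area is the caller's choice.
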