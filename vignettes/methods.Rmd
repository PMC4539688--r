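---
title: "Detecting differential chromatin interactions with hicdelta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differential chromatin interactions with hicdelta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicdelta)
```

## The problem

Hi-C couples chromatin conformation capture with paired-end sequencing: DNA
is cross-linked, digested with a restriction enzyme, and fragment ends held
together in the same chromatin complex are filled in and ligated. Each
sequenced pair therefore reports physical proximity between two genomic
loci, and the collection of read pairs samples the genome-by-genome
*interaction space*. Rather than calling "significant" interactions within a
single sample — which requires elaborate background models for GC content,
mappability and fragment-length biases — `hicdelta` tests whether the
intensity of each interaction *changes* between biological conditions. In a
differential comparison the same genome is present in every library, so
sequence-driven biases largely cancel, and the question becomes a familiar
count-regression problem with biological replication.

## From reads to counts

**Digest model.** A palindromic restriction enzyme with recognition
sequence of length $\ell$ and top-strand cut offset $p$ leaves a 5'
overhang of length $L = \ell - 2p$. After fill-in and blunt ligation the
junction carries the *ligation signature*: the first $p + L$ bases of the
site followed by the site from position $p+1$ onward (HindIII: AAGCTT with
$p = 1$ gives AAGCTAGCTT). Where the point "cut site" lies within the
recognition occurrence is not standardized across tools; we place it at
the site centre — the blunt-end position after fill-in — which is symmetric
and enzyme-agnostic. Fragments are the half-open intervals between
consecutive centres and tile each chromosome exactly; we do not let
neighbouring fragments overlap by the overhang, a convention some other
implementations use, and note that fragment indices may differ from theirs
by that choice.

**Chimeric reads.** A read sequenced across a ligation junction has 5' and
3' segments from different loci. Since only the 5' segment's locus is
informative (the mate covers the other side), reads containing the
signature are split at its centre before alignment; the first occurrence is
used when several are present. A property-style test confirms on simulated
junction reads that exact matching of the pre-split 5' segment recovers the
true 5' locus at least as often as matching the full-length read.

**Quality control.** Read pairs pass a fixed cascade: MAPQ/unmapped checks,
duplicate flags (honoured from the aligner/Picard, never recomputed),
inferred sequencing-fragment size (sum of each read's distance to the next
cut in its own direction; pairs above 600 bp are non-specific cleavage
products), then orientation filters for intra-chromosomal pairs:
inward-facing pairs closer than 1 kbp are dangling ends, outward-facing
pairs closer than 25 kbp are self-circles. The cascade order is fixed by the package
(no community convention exists) so that removal statistics are
reproducible; the size test is strict (`> 600` removed, 600
retained); gaps are 5'-to-5' distances; same-strand and inter-chromosomal
pairs are exempt from the orientation filters. Technical replicates are
pooled by concatenating pair stores before counting.

**Bin pairs.** The genome is partitioned into bins of nominal width with
each interior boundary moved to the nearest restriction cut (ties towards
the larger coordinate; colliding boundaries deduplicated), because ligation
always occurs at fragment ends and sub-fragment positions carry no
information. The count $y_{bi}$ for bin pair $b$ in library $i$ is the
number of read pairs with one read in each bin; only observed bin pairs are
materialized since the space is quadratic in the bin count. Marginal counts
treat libraries as single-end — a diagonal bin pair contributes twice to
its bin — and serve as a coverage/copy-number proxy.

## Filtering

The filter statistic is the average abundance: the log2 count-per-million
across libraries with a library-size-scaled prior (default 2), which is
approximately independent of the differential test under the null. Three
strategies are provided:

* **direct** (default, fold 5): keep bin pairs whose abundance exceeds the
  median abundance of *all* inter-chromosomal bin pairs — an estimate of
  the non-specific ligation rate, since chromosome territories make most
  inter-chromosomal contacts spurious — by more than $\log_2$(fold).
  Unmaterialized (zero-count) bin pairs enter this median analytically via
  the universe size, so no quadratic memory is needed.
* **trend**: keep intra-chromosomal pairs above a loess fit of abundance on
  log10 genomic distance, removing the distance decay driven by genome
  compaction; inter-chromosomal pairs fall back to the direct threshold.
* **peak**: keep pairs enriched over their own 2-D neighbourhood, computed
  as the pixel abundance minus the largest abundance among the square rings
  at Chebyshev radii $1..r$ (truncated at edges and at the diagonal).
  Peak-calling neighbourhood geometry and thresholds vary between tools;
  both are exposed as parameters here, and the simple ring decomposition
  (not donut/quadrant calling with Poisson statistics) is a deliberate
  simplification.

## Normalization as GLM offsets

No normalization alters the counts. Every scheme produces per-observation
offsets $o_{bi} = \log N_i + a_{bi}$ (natural log; $N_i$ the library size,
i.e. total retained pairs), with the adjustments $a_{bi}$ mean-centred
across libraries per bin pair because offsets are only identified up to an
additive constant. M/A diagnostics are in log2; the $\ln 2$ conversion is
applied at the boundary.

* **loess** offsets remove trended biases: per library, M (log2 fold change
  over the across-library mean log-abundance, priors added for low counts)
  is regressed on abundance A with loess; the fitted value becomes the
  adjustment. Mean-centring per bin pair preserves average abundance so
  filtering and normalization commute in expectation. With span $\to$ 1 and
  a flat trend this reduces to a scaling factor.
* **scaling** offsets compute one factor per library from a doubly-trimmed
  mean of M (default trims: 30 % on M, 5 % on A), anchored to a unit
  geometric mean — for designs where a trended difference is biology, not
  bias.
* **cnv** offsets remove copy-number-driven effects: each bin pair carries
  the marginal log2 fold changes of its two anchor bins as covariates
  (ordered, so the surface is symmetric in the anchors) and its own log2
  fold change as response; a local-linear `loess` surface over the two
  covariates (span 0.1) supplies the adjustment. The small span is needed
  because CNV structure forms tight clusters in covariate space; a summed
  single covariate is available as a fallback for sparse data. For more
  than two libraries each is fitted against the first as reference.
* **iterative correction** (matrix balancing) alternately rescales rows and
  columns of a symmetric contact matrix until the coefficient of variation
  of the row sums drops below tolerance, optionally excluding a fraction of
  lowest-coverage bins. It is provided as a diagnostic/alternative and is
  not chained into the GLM offsets by default.

## The statistical model

Counts follow a quasi-negative-binomial model. The mean is log-linear,
$\log \mu_{bi} = \sum_j x_{ij}\beta_{bj} + o_{bi}$, with an arbitrary
full-rank design matrix, so paired, blocked and multi-group experiments are
all handled. The variance is
$\mathrm{var}(y_{bi}) = \sigma^2_b\,(\mu_{bi} + \phi_b\,\mu_{bi}^2)$:
$\phi_b$ is the NB dispersion shared locally across bin pairs (its square
root is the biological coefficient of variation), and $\sigma^2_b$ a
bin-pair-specific quasi-likelihood scale around it.

**GLM fitting** maximizes the NB likelihood per bin pair with vectorized
Fisher scoring and Levenberg-style damping (ridge on the information
diagonal, increased tenfold on any deviance increase), converging on
relative deviance change below $10^{-8}$ within 100 iterations;
non-converged fits are flagged and the last iterate returned. All-zero bin
pairs give NA (they should have been filtered). The fitter reproduces
`glm(family = poisson)` at $\phi = 0$ and an independent NB reference to
$10^{-4}$ in the test suite.

**Dispersion trend.** $\phi$ is estimated on a log-spaced grid
($10^{-6}$–2, 21 points) by the Cox–Reid adjusted profile likelihood
(likelihood minus half the log-determinant of the information), summed
within ~20 equal-count abundance bins and maximized with quadratic
interpolation; a lowess curve through the per-bin estimates, evaluated with
clamped extrapolation, gives the trend. On simulated data the trend
recovers constant $\phi = 0.05$ within [0.04, 0.06] at 10,000 bin pairs and
collapses below $10^{-3}$ for Poisson data.

**QL dispersions and the EB squeeze.** The raw $\sigma^2_b$ is the deviance
at the trended $\phi$ over the residual df (a deliberate choice over
Pearson estimators for small-count stability). Raw values are unstable with
few replicates, so an empirical-Bayes step squeezes them towards an
abundance trend with weight $\mathrm{df}/(\mathrm{df} + d_0)$. Two details
matter and are package decisions: the trend takes its *shape* from a loess
fit on the log scale but its *location* from a robust first-moment anchor
(the median of raw/trend matched to the median of $\chi^2_{df}/df$),
because the sampling distribution of NB deviances is only approximately
chi-squared and a pure log-scale bias correction overshoots; and the prior
df $d_0$ comes from matching the winsorized variance of the log residuals
against an equally winsorized quantile-grid reference of the null
$\log(\chi^2_{df}/df)$ distribution (robust mode, default on), since the
raw log spread is heavy-tailed enough to make the plain moment estimator
flip between extremes. If the residual spread is exactly zero the raw
values are taken as exact ($d_0 = \infty$, no squeeze). These are
documented approximations validated by calibration, not bit-level copies of
any reference implementation.

**Testing.** The QL F-test compares the deviance drop for a contrast
(1 df; the null design is the full design projected onto the contrast's
null space) against the squeezed $\sigma^2_b$, with denominator df equal to
residual plus prior df. Log2 fold changes are reported for 1-df contrasts
and p-values are BH-adjusted. On zero-effect simulations run through the
full pipeline the p-values are uniform (KS combined across five iterations)
and the rejection rate at 5 % is 5 %.

## Consolidation and visualization

Adjacent significant bin pairs are clustered by single linkage with
Chebyshev adjacency (both anchor gaps within `max_gap`); each cluster is
reported once with its bounding box, Simes-combined p-value, BH-adjusted
FDR across clusters, and the log fold change of its smallest-p member.
Analyses at several bin sizes are consolidated by nesting fine bin pairs
into the coarse "parent" whose bins contain their anchor midpoints; each
parent pools its own p-value (when tested) with all children in one flat
Simes combination; pooling flat rather than hierarchically is a package
decision. Whether clustering happens before or
after significance selection is exposed (`significant_only`), defaulting to
clustering all supplied pairs. Plaid plots rasterize read pairs into
fixed-size boxes with intensity linear in count divided by library size, so
panels from libraries of different depth are comparable.

## The simulator: what it emulates, and what it does not

`simulate_counts()` draws baseline expected counts log-uniformly on
[8, 512] — chosen so a 10,000-bin-pair library sums to roughly the nominal
$10^6$ pairs — places them on randomly chosen canonical bin pairs of a
synthetic two-chromosome interaction space (75 + 75 bins of 100 kbp), spikes
10 % of bin pairs as true DIs with a fold change of 4 (direction random,
split symmetrically across the two groups so average abundance is stable),
and draws NB counts with $\phi = 0.05$ per replicate, two replicates per
group. All constants live in one place and every draw is governed by a
single seed. `simulate_chimeric_reads()` joins the filled-in ends of two
restriction fragments so the junction carries the exact signature, samples
a read across it at a random offset, and records the true 5' locus.

The simulator emulates overdispersed replicate counts, sparse
materialization, intra/inter structure, trended and CNV biases (by
construction in the relevant tests) and chimeric junctions. It does not
emulate distance-dependent contact decay, domain structure, GC/mappability
bias, duplicate reads or sequencing error; passing tests therefore
demonstrate the statistical machinery under its stated model, not
performance on any real library.

`benchmark_detection()` reruns the comparison between the QL pipeline and a
binomial comparator: an exact two-sided binomial test on within-group
pooled libraries (the two-library statistic used by simpler tools), plus
the ad hoc workaround of intersecting detections across all between-group
replicate pairings. Five iterations are averaged. The binomial test models
only sequencing variability, so with $\phi > 0$ its observed FDR exceeds
the nominal level by an order of magnitude and the intersection does not
restore control, while the QL pipeline stays at or below nominal with at
least as many true detections — the qualitative ordering the acceptance
script recomputes.

## Numerical and interface decisions

* Coordinates are 0-based half-open internally, 1-based inclusive in every
  user-facing table; BEDPE export is 0-based.
* Pair stores are TSV tables with a JSON QC report; counts serialize as TSV
  and BEDPE; bins export as BED via `rtracklayer`.
* Problem sizes in the test suite: unit tests run at 1,500–6,000 bin pairs;
  the calibration studies at 10,000 bin pairs with five iterations, the
  sizes at which the reported properties were computed.
* `bh_adjust()` delegates to `stats::p.adjust`; the test suite checks it
  against an independently hand-coded step-up.
* The iterative-correction exclusion fraction drops exactly
  `floor(f * n)` lowest-coverage bins before balancing; excluded bins get
  `NA` bias.
* Degenerate inputs: empty reads warn and return nothing; all-equal
  distances in the trend filter fall back to a mean threshold with a
  warning; an all-zero contact matrix, non-symmetric input, or a peak
  radius exceeding the chromosome are errors.

## Known limitations

* The EB moment calibration is tuned for the small-replicate regime
  (residual df 1–4) typical of Hi-C; with many replicates the winsorized
  reference correction is slightly conservative.
* At very low counts (means below ~8) the deviance-based F statistic
  inherits mild conservatism; the recommended abundance filters remove that
  regime in practice.
* The binomial comparator reproduces only the test of the referenced tool,
  not its background model or software pipeline.
* Only palindromic 5'-overhang (or blunt) enzymes are supported; multi-
  enzyme digests and fragment-resolution counting are out of scope.
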