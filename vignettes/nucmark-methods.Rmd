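---
title: "Identifying constitutive markers of brain nuclei from paired-region microarrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying constitutive markers of brain nuclei from paired-region microarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucmark)
```

## The problem

Discrete brain nuclei — the song-control nuclei of songbirds are the
motivating case — differ from the tissue that surrounds them in the
constitutive expression of many genes. Screening for such *markers* with
microarrays sounds routine, but the probe libraries of the relevant
platforms (EST-derived cDNA collections and 60-mer oligo sets) are full of
probes that cannot report on a single gene: clones created by second-strand
oligo-dT priming (recognizable by a 5' poly-T run, and probing the wrong
strand), probes aligning to several loci on different chromosomes, probes
that fail to align to the genome at all, and probes whose annotation
ignored strand. On top of that, a blind ANOVA-plus-FDR analysis leaves the
significance threshold unanchored: the right cutoff depends on the contrast
and the platform, and an independent source of truth — in-situ
hybridization images scored as differential or non-differential — can
calibrate it.

`nucmark` implements that full pipeline as reusable, tested R functions:

1. **Probe curation** — poly-T artifact screen, alignment filters
   (identity ≥ 95% for cDNA/ESTs, score ≥ 25 for oligos; removal of probes
   hitting two or more *named* chromosomes; retention, with a flag, of
   high-identity secondary hits on the unplaced-scaffold pseudo-chromosome
   `chrUn`, which are presumed allelic), and strand-aware annotation
   against gene models (overlap, else nearest same-strand model within
   3 kb for cDNA / 5 kb for oligos; antisense-only overlaps are surfaced
   but never assigned).
2. **Expression statistics** — "half" background correction
   (foreground − background, non-positive values set to 0.5), print-tip
   loess normalization of M on A per array, orientation of all log-ratios
   as log2(sample/reference) in the dye-balanced common-reference design,
   low-signal and high-variance filters for the oligo platform, moderated
   t-statistics, and BH or Storey q-values.
3. **Cutoff calibration** — class-conditional p-value histograms over an
   independently labeled gene set, with the cutoff chosen on the histogram
   edges and a p < 0.05 default when no labels exist.
4. **Gene scoring** — collapsing of redundant probes (>75% reciprocal
   overlap, single linkage, averaged p and M), the inclusive ≥ 50%
   majority rule, direction assignment with explicit conflicts, and
   merging with in-situ calls, which win on conflict.
5. **Marker intersection and enrichment** — common assessed-gene universe,
   exact Venn partition across contrasts, and hypergeometric
   over-representation analysis against GMT collections (minimum overlap
   2, retention at p ≤ 0.01, reporting flag at q < 0.05).
6. **Synthetic data** — a generator that emulates the paired
   laser-capture designs end to end, so every stage above is testable
   against a known ground truth without any external download.

The exported functions are the interface; a typical analysis is a short
script (see the README for a worked example), so no shell entry points are
shipped.

## The moderated t-statistic

For probe $g$ with pooled two-group residual variance $s_g^2$ on $d_g$
degrees of freedom, the variance prior $s_0^2$ with prior degrees of
freedom $d_0$ is estimated by the method of moments on $\log s_g^2$
(digamma/trigamma matching, with Newton inversion of the trigamma
function). The posterior variance

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}$$

replaces $s_g^2$ in the t-statistic, which is referred to a t distribution
on $d_0 + d_g$ degrees of freedom. Both hyperparameters can be overridden:
$d_0 = 0$ recovers the ordinary pooled t exactly, and $d_0 = \infty$ the
fixed-variance z-like form — both limits are pinned by tests, and the
default estimates agree with `limma::eBayes` to machine precision (limma
serves as an independent cross-check, never as the implementation; the
module's contract requires the explicit $d_0$ control that `eBayes` does
not expose). When the spread of $\log s_g^2$ is no larger than chi-square
sampling alone explains, the moment equation has no positive solution and
$d_0 = \infty$ is used (complete shrinkage).

With two groups these moderated t-tests coincide with one-way ANOVA group
comparisons ($t^2 = F$), so one implementation serves both descriptions of
the analysis.

Storey's q-value rescales BH by $\hat\pi_0$, estimated as the median over
$\lambda \in \{0.05, \dots, 0.95\}$ of
$\#\{p > \lambda\}/(m(1-\lambda))$, clipped to $(0, 1]$. Note that unlike
plain BH, a Storey q-value may drop below its p-value when
$\hat\pi_0 < 1$.

## Cutoff calibration

Probe-level p-values (a gene contributes one per retained probe) are split
by the validation label of their gene; excluded labels — sections whose
folds, artifacts, or absent signal made visual evaluation impossible — are
dropped. Over candidate cutoffs at the histogram bin edges (20 equal-width
bins plus refined edges at 0.001, 0.005, 0.01, 0.02 to resolve the small-p
region where useful cutoffs actually live), the chosen cutoff maximizes
TPR − FPR (Youden's J), a reproducible stand-in for the visual choice of
"the highest proportion of true vs. false positives"; ties break toward
the smaller, more conservative cutoff, and a manual override is available
to reproduce a visually chosen value. If the two class distributions are
indistinguishable (max J ≤ 0) the function warns and returns the standard
0.05 default, which is also used for contrasts with no labels at all.

## The low-signal filter

Each probe is summarized by the larger of its two per-region mean
intensities (a probe detecting expression in either region is
informative; the mean over all samples is available as an option). Probes
are ranked high to low and the rank-intensity curve is inspected for the
shoulder separating the expressed regime from the near-background plateau.
The automation of that visual inspection works on the curve smoothed by a
running mean of width $w$ (1% of probes, minimum 25):

* the steepest point of descent is located;
* a shoulder is declared only if that slope is at least 4× steeper than
  the curve's slope on both flanks — a unimodal, featureless curve has no
  such point, and the filter falls back to removing nothing (with a
  warning);
* the cutoff statistic is computed where the curve has flattened back out
  (slope recovered to a quarter of the steepest slope): the mean over the
  next $2w+1$ ranked probes plus 2.5 times their standard deviation.

Placing the statistics window on the background plateau, rather than
centering it on the steepest point, matters: a window straddling the cliff
has a large standard deviation, and "mean + 2.5 SD" would then cut into
the expressed regime. An earlier candidate rule — the point of maximum
perpendicular distance between the curve and its end-to-end chord — was
rejected for exactly that reason: on a mixture of expressed
$\mathcal N(10,1)$ and background $\mathcal N(4,0.5)$ probes it lands in
the lower tail of the expressed mode and the resulting threshold discards
about 7% of expressed probes, where the plateau rule loses essentially
none while still removing >95% of the background regime.

## The high-variance filter

Probes with stdev/mean above twice the population average are removed; the
boundary is strict (a probe exactly at 2× is retained), and CVs are
computed on the unlogged scale. One interpretation choice deserves
emphasis: computed across *all* samples of a contrast, the CV of a genuine
4-fold marker (≈ 0.6 under the study conditions) sits right at twice the
population mean (≈ 0.3), so the filter would delete the very signal the
screen is looking for. `nucmark` therefore computes the CV within each
region and summarizes a probe by its larger region CV; a between-region
fold change then never masquerades as noise, while genuinely unstable
probes are still caught. The single-group behaviour is available by
omitting the `group` argument.

## Majority-rule scoring

Probes annotated to the same gene are grouped by single linkage on the
">75% of the shorter probe" overlap relation (transitively: if A overlaps
B and B overlaps C, all three are one group even if A and C barely
overlap); each group contributes one averaged p and one averaged M. The
averaged p is compared to the cutoff after averaging, including for
direction-discordant members. A gene is differential when at least 50% of
its unique groups are significant — inclusively, so one significant group
out of two suffices — and non-differential otherwise; genes with no
retained probes are not assessed. Direction is unanimous-up, unanimous-
down, or an explicit conflict; conflicts are surfaced for manual review,
never majority-voted away. In-situ calls, when supplied, override array
calls on conflict (flagged discordant) and fill in genes the arrays could
not assess.

## The synthetic-data generator

The generator emulates the structure the pipeline assumes: a small genome
(four named chromosomes plus `chrUn`), gene models with strand, 1–6 probes
per gene placed inside their gene's span, and per-probe artifact classes
planted at configurable rates (defaults: 5% poly-T, 3% multi-locus, 2%
unaligned, 5% benign chrUn secondaries — together close to the ~7–13%
removal rates reported for the real libraries). Intensities follow a
log-normal model: per-probe baselines from a two-component mixture
(expressed $\mathcal N(10,1)$, near-background $\mathcal N(4,0.5)$ on the
log2 scale, 20% near background by default — the minimal structure that
exercises the low-signal filter), per-channel noise SD 0.4, additive local
background around $2^7$ for the two-channel platform, a smooth
per-print-tip intensity-dependent dye bias for the normalization stage to
remove, and dye-balanced common-reference arrays. Differential genes are
shifted by their true log2 fold change (default 2.0, i.e. a strong 4-fold
nucleus marker) in nucleus samples only. Default design size is 6 sample
pairs per contrast, matching the larger of the emulated designs (the real
contrasts ranged from 3 to 9 pairs).

Validation labels sample a configurable fraction of genes (default 30%,
roughly 320 labeled genes out of a ~1000-gene universe), flip a fraction
(default 5%) to model observer error, and mark a fraction excluded. Gene
sets are drawn uniformly (null collections) or with a configurable odds
ratio toward differential genes (enriched collections).

One master seed derives per-stage substreams, and the same seed and
configuration reproduce byte-identical outputs.

Real-data features the generator deliberately does not model: spatial
array layout beyond the print-tip index (no scanner images), probe
sequence-composition effects, correlated cross-hybridization, and RNA
degradation gradients. Passing tests therefore demonstrate the pipeline's
statistical and bookkeeping correctness under the stated noise model, not
robustness to every artifact of physical arrays. The per-pair (per-bird)
random effect is available (`pair_sd`) but defaults to 0: the true
nucleus–surround covariance within a bird is unknown, and the analysis
deliberately treats arrays as two independent groups.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally and in BED output; 1-based
  inputs must be converted at parse time.
* "Different named chromosomes" excludes `chrUn` by definition; two
  passing alignments on the *same* named chromosome do not remove a probe.
* The poly-T rule is operationalized as "a run of ≥ 15 T starting within
  the first 5 nt": the published description gives the run length but no
  start tolerance, and 5 nt absorbs vector-trimming slop.
* Proximity windows are measured edge-to-edge between the probe alignment
  and the gene model.
* Loess uses span 0.3, degree 1, 3 robustness iterations; tip groups with
  fewer than 10 probes use the global curve; a group with all-identical
  A values has its median M subtracted.
* Background correction keeps small positive differences as data: only
  zero or negative differences become 0.5.
* A probe group's averaged p is compared to the cutoff after averaging.
* ORA q-values are BH across every set passing the minimum overlap (the
  eligible tests); the output table is then restricted to p ≤ 0.01 unless
  `report_all = TRUE`.
* An optional Jaccard-style collapse of redundant gene sets is *not*
  provided: pruning redundant or generic pathways is a judgment call left
  to the analyst.

## Problem sizes used by the test suite

The suite validates the pipeline at sizes chosen to make sampling error
negligible while keeping a full run in the order of a minute or two:
10,000 probes for null-uniformity and type-I checks (n = 3 per group),
1,000 genes × 2 probes for the end-to-end recovery runs (10% differential
at log2FC 2, 6 pairs), 100 seeded replicates for cutoff-recovery and
label-noise robustness, 1,000 random probe configurations for the
majority-rule oracle comparison, and exhaustive hypergeometric enumeration
up to a 20-gene universe.

## Known limitations

* Print-tip loess attenuates strong one-sided regulation at the extremes
  of the intensity range (regulated probes dominate the curve locally);
  with 10% of genes differential at 4-fold, recovered fold changes on the
  two-channel platform are mildly shrunk toward zero. This is inherent to
  within-array loess normalization, not specific to this implementation.
* The Youden-maximizing cutoff is a deterministic surrogate for a visual
  choice; with heavily contaminated label sets it can sit one refined bin
  away from where an expert would draw the line. The manual override
  exists for exactly that case.
* Between-array normalization (quantile/Aquantile) and array weights are
  out of scope; single-channel inputs are assumed pre-normalized.
* The iterative manual re-annotation loops of real curation efforts are
  not automated; the pipeline runs one pass and flags conflicts.
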