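---
title: "Methods: expression subtyping and copy-number calling in gliopipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression subtyping and copy-number calling in gliopipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliopipe)
```

gliopipe implements the computational arm of a common study design in mouse
glioma modelling: bead-array expression profiles of neural stem cells across
genotypes (wild type, a p53-pathway mutant, and a double mutant), a
cross-species comparison of the mutant's expression profile against human GBM
subtype centroids, SNP-array copy-number calling on the same cells, and
rank-based comparisons of human cohort z-scores. Every stage can be run on
synthetic inputs with planted truth, which is how the package tests itself.

## Expression preprocessing

**Variance stabilization.** Raw bead intensities are mapped to the log2
scale with the generalized-log transform

$$g(x) = \log_2\!\frac{x + \sqrt{x^2 + c^2}}{2},$$

which equals $\log_2 x$ at $c = 0$ and flattens the variance inflation of
low intensities for $c > 0$. Bead-array-specific variance stabilization
needs bead-level variance estimates that summary matrices do not carry; the
glog has the same variance-stabilizing intent, a closed form, and is exactly
testable, which is why it is the transform offered here. `glog_c` is on the
raw intensity scale; 0 is the default because the synthetic data are
generated on the log scale and back-transformed.

**Quantile normalization** replaces each value by the across-sample mean of
same-rank values. Ties within a sample receive the mean of the reference
values their ranks span, so tied inputs stay tied and the operation is
idempotent. The implementation is ten lines of base R rather than a wrapper
because this exact tie rule is part of the contract; the limma implementation
is used as an independent cross-check on tie-free data in the test suite
(its tie handling interpolates mid-ranks, which differs for ties spanning
three or more ranks).

**Technical duplicates** are averaged per replicate group after
normalization, with the Pearson correlation of every within-group pair
reported. The correlation floor (default 0.996) is a QC check, not a filter:
pairs below it warn (error only in strict mode), because duplicate
correlation in this design is verified, never used to drop arrays.

**Fold changes and rescue.** Per-gene log2 fold change is the condition mean
minus the reference mean on the collapsed matrix. A gene is *deregulated*
when $|\mathrm{logFC}| > \log_2(1.5)$ — "more than 1.5-fold" is read as a
strict inequality. A deregulated gene is *rescued* in the second comparison
(double mutant vs reference) when $|\mathrm{logFC}_{2}| \le \log_2(1.5)$:
returning to within the fold band of the reference. The non-strict
complement is a deliberate choice — the two rules partition the axis — and
the band itself is this package's explicit operationalization of "returned
to wild-type levels"; no exact numeric criterion for that phrase exists to
inherit, so the fold band is reused for symmetry.

## Cross-species subtype classification

A mouse fold-change profile is mapped onto a human GBM centroid signature
(Proneural, Neural, Classical, Mesenchymal) through a symbol map; unmapped
signature genes are dropped and a mapped fraction below 50% warns. Several
profile genes landing on one signature symbol are averaged (`collapse =
"mean"`), keeping the mapped profile deterministic regardless of map order.

**Distance.** The default metric is $1 - \rho$ with Spearman's $\rho$,
selectable to Pearson or Euclidean. Rank correlation is the default because
the profile and the centroids come from different species and platforms, so
only the ordering of signature genes is comparable; any strictly monotone
rescaling of the profile leaves the distance unchanged.

**Bootstrap null.** The null resamples the profile's fold-change values with
replacement and assigns them to signature positions *without preserving gene
pairing*, keeping centroids fixed; B = 1000 by default. Preserving pairing
would center the null on the observed distance and no observed distance
could ever sit in a lower tail, so the unpaired scheme is the only one that
yields a usable no-association null. A without-replacement permutation
variant is available. When the assignment space $n^n$ is small the null is
enumerated exactly, which the tests exploit on 3-gene toys.

**Test and assignment.** The one-sided p-value uses the add-one rule
$p = (1 + \#\{d_{null} \le d_{obs}\})/(B + 1)$, so $p \ge 1/(B+1)$ and never
zero. A subtype is significant when its observed distance falls below the
5% quantile of its null. Assignment minimizes the *relative* distance
(observed over expected-under-null), which normalizes away per-subtype
differences in null distance scale; ties break by raw distance, then label
order. Raw-distance assignment and a pooled null (all subtype-centroid
distances combined) are options because the per-subtype/pooled choice is
genuinely open; per-subtype is the default as the more conservative,
self-normalizing reading.

Under no association, the bootstrap null differs slightly from the
distribution of the observed statistic (resampling with replacement
introduces ties into the ranks), so calibration is a property to verify
rather than assume; the test suite checks that the per-subtype rejection
rate at the 5% level stays within [0.03, 0.07] over 500 null runs.

## Copy-number calling from LRR tracks

The caller ingests marker tracks (marker, chromosome, position, LRR, BAF,
GC fraction of the 1 Mb window centered on the marker); deriving LRR/BAF
from raw arrays is upstream and out of scope. Markers that do not probe
allelic balance are dropped at ingestion. Only autosomes are fitted and
called.

**GC-waviness correction.** Genomic waviness is the long-range LRR
oscillation that tracks regional GC — an array artifact. With
$\tilde g = \mathrm{GC} - \mathrm{median}(\mathrm{GC})$, the correction
subtracts $c^* \tilde g$ where $c^*$ minimizes
$\mathrm{Var}(\mathrm{LRR} - c\,\tilde g)$; the quadratic has the unique
minimizer $c^* = \mathrm{Cov}(\mathrm{LRR}, \tilde g)/\mathrm{Var}(\tilde
g)$, so corrected variance never exceeds the input variance. The fit is
genome-wide per sample (per-chromosome fitting is a config option): a single
chromosome often carries only one or two smooth GC excursions, and a real
copy-number segment that happens to align with one of them can then
masquerade as wave. Genome-wide, many independent excursions make the
coefficient identifiable; the same reasoning means coefficient *recovery*
should be benchmarked on wave-plus-noise tracks, while CNV-bearing tracks
are scored on downstream state accuracy.

**Segmentation** is recursive binary splitting: within each candidate
segment the split maximizing the pooled two-sample t statistic is accepted
when a permutation p-value (default 100 permutations) is below `alpha`
(default 0.01) and both sides hold at least `min_markers` (default 5)
markers. Because a greedy split is localized while the flank still contains
a second changepoint, every interior boundary is then re-fit as the single
best split of its two adjacent segments, iterated to a fixed point — the
same refinement idea used by circular binary segmentation. Finally the
SD-undo rule merges adjacent segments, weakest pair first, while their mean
difference is below `undo_sd` (default 3) times the noise SD, estimated
robustly from successive marker differences as
$\mathrm{median}(|\Delta|)/(\sqrt2 \cdot 0.6745)$ so that true changepoints
barely inflate it. This pipeline is a documented approximation of CBS with
SD-based split pruning; exact equivalence is not claimed. A consequence
worth knowing: with noise SD $\sigma$, shifts below $\approx 3\sigma$ are
*by construction* undone at the default `undo_sd = 3`; recovery benchmarks
therefore plant shifts with clear margin above that line (e.g. $\pm 0.8$ at
$\sigma = 0.2$).

**State calling** maps segment mean LRR through four ordered cut points,
default $(-1.0, -0.3, 0.3, 0.9)$, onto the conventional coding 0 homozygous
loss, 1 hemizygous loss, 2 normal, 3 gain, 4 amplification. Fixed thresholds
replace mixture-model posterior calling: the defaults respect log2
single-copy expectations at moderate purity (single-copy loss
$\log_2(1/2) = -1$ attenuated by normal-cell content, single-copy gain
$\log_2(3/2) \approx 0.58$) and are prominently tunable, since any fixed
choice encodes a purity assumption.

**Reporting.** Only non-normal segments strictly longer than 1 Mb
(`end - start + 1` on 1-based inclusive marker coordinates) are reported.
Multi-sample results can be compressed to comparable regions: the union of
all samples' breakpoints per chromosome, with each region carrying every
sample's covering state. BED export shifts to 0-based half-open coordinates.

## Cohort z-score comparisons

Expression z-scores standardize one gene against a control distribution
(unbiased SD). Group contrasts — mutation status, or a two-cell subtype
partition such as GCiMP + Proneural versus the rest — use the two-sided
Wilcoxon rank-sum test for independent groups: exact enumeration when the
combined size is at most `exact_cutoff` (default 12) and ties are absent,
otherwise the normal approximation with mid-ranks, tie correction and
continuity correction. Fully tied data returns p = 1. Cross-platform
agreement is Spearman correlation over the sample overlap (mid-ranks), so it
is invariant to monotone transforms of either platform's scale.

## The synthetic-data generators

The generators define the study conditions under which the package is
tested; their defaults are fixed, not tuned per test.

* **Expression** (`simulate_expression`): per gene one latent log2 baseline
  from U(4, 14) — wide enough that technical-duplicate correlation
  concentrates near 0.999, emulating a design where duplicate correlation
  exceeds 0.996 throughout — plus condition effects, with `n_tech_dups`
  independent Gaussian reads (SD 0.1 by default) of each latent sample,
  emitted as raw intensities $2^x$. Planted genes get baselines with
  headroom so the effect stays inside the dynamic range: a probe at the
  intensity ceiling cannot display up-regulation, and quantile
  normalization would clip it. Defaults emulate one pooled biological
  sample per genotype with two technical duplicates.
* **Marker tracks** (`simulate_marker_track`): evenly spaced markers, a
  smoothed-Gaussian-random-walk GC fraction clipped to [0.3, 0.7], LRR =
  segment shift + wave coefficient × centered GC + Gaussian noise (SD 0.15
  by default, typical for genotyping arrays), BAF drawn around the
  heterozygosity pattern of the planted state. Truth segments are validated
  (sorted, non-overlapping, states 0–4).
* **Cohorts** (`simulate_cohort`): wild-type z-scores standard normal, a
  fixed `round(fraction × n)` mutant group shifted by `effect`; subtype
  labels from a categorical distribution resembling published GBM cohort
  composition (GCiMP 9%, Proneural 28%, Neural 16%, Classical 22%,
  Mesenchymal 25%).
* **Centroids and gene maps** (`simulate_centroids`, `simulate_gene_map`):
  standard-normal centroid values over a synthetic signature, and a
  source→target symbol map covering a configurable fraction (default 80%,
  echoing the incompleteness of cross-species symbol matching).

All generators are pure functions of their parameters and seed (R's default
Mersenne–Twister), so identical calls are bit-identical.

**What the generators do not emulate.** Bead-level artifacts, probe
sequences, background, batch structure, intensity-dependent variance beyond
what the glog addresses, correlated gene–gene expression, LRR
autocorrelation beyond the GC wave, and subclonal (non-integer) copy number.
Passing tests therefore demonstrate the correctness of the computations and
their behavior under idealized noise, not performance on any particular
real dataset.

## Numerical choices and degenerate inputs

* Fold selection is strict (`>`), rescue non-strict (`<=`), so the two
  classify every gene exactly once.
* Quantile-normalization ties group by exact value equality; idempotence
  holds to machine precision.
* Zero-variance GC makes the waviness coefficient 0 with a warning (no
  correction is possible); non-autosomal markers pass through uncorrected.
* A chromosome with fewer than `min_markers` markers becomes a single
  segment with a warning. A zero-variance segmentation input yields one
  segment. Noise SD 0 disables the undo rule rather than dividing by zero.
* Constant bootstrap resamples under a correlation metric are redrawn (the
  count is reported); in enumeration mode they are dropped.
* Assignment tie-breaks: relative distance, then raw distance, then label
  order — fully deterministic.
* Per-stage pipeline seeds derive arithmetically from the master seed and
  stay below $2^{31}$.

## Problem sizes used by the test suite

The suite exercises 2000-gene expression matrices (20 seeds for exact
planted-gene recovery), 2000–3600-marker tracks (50 seeds for the waviness
oracle against a 100,001-point variance grid, 100 seeds for segmentation
recovery, 20 for wave-invariance), 100 seeds at B = 1000 for planted-subtype
recovery, and 500 null runs at B = 1000 for test calibration — sizes chosen
so each property is measured with useful precision while the whole suite
runs in minutes on one core.

## Known limitations

* The segmentation engine approximates CBS; on signals with many closely
  spaced changepoints the greedy splitting order can differ from CBS's
  circular statistic.
* Fixed LRR thresholds tie state calls to an implicit purity; heavily
  contaminated samples need re-tuned cut points.
* The genome-wide waviness fit assumes copy-number changes occupy a
  minority of markers; a genome dominated by aberration would bias the
  coefficient (per-chromosome fitting does not fix this and is more
  confoundable, not less).
* The rescue criterion is a fold band, one reasonable operationalization of
  "returned to reference levels" among several.
* Bootstrap-test calibration is empirical, not exact; the add-one p-value
  is conservative at very small B.
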