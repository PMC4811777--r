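# gliopipe

Expression subtyping and SNP-array copy-number pipelines for glioma model
studies.

## What problem this solves

Mouse glioma models are routinely characterized with three computational
analyses that are usually stitched together ad hoc: (1) bead-array expression
preprocessing and a fold-change screen for genes deregulated in a mutant
genotype — and "rescued" in a double mutant; (2) a cross-species comparison
of the mutant's expression profile against the human GBM subtype centroids
(Proneural, Neural, Classical, Mesenchymal), with a resampling test for
whether the nearest centroid is significantly close; and (3) copy-number
calling from SNP-array Log-R-Ratio (LRR) tracks, which requires correcting
the GC-correlated "genomic waviness" artifact before segmentation. A fourth,
companion analysis compares expression z-scores between groups of a human
cohort (e.g. TP53-mutant vs wild type) with rank tests.

gliopipe implements all four as tested, scriptable R functions, plus a
synthetic-data module that generates every input with known planted truth so
the whole chain can be validated end to end. It is aimed at computational
biologists analyzing mouse neuro-oncology models against human GBM
references.

## The core methods

* **Fold-change screen.** After a generalized-log transform
  `log2((x + sqrt(x^2 + c^2))/2)` and quantile normalization, technical
  duplicates are averaged (pairwise Pearson r reported against a 0.996 QC
  floor) and per-gene log2 fold changes vs the reference genotype are
  computed. Deregulated: `|logFC| > log2(1.5)` (strict). Rescued in the
  second comparison: `|logFC₂| ≤ log2(1.5)`.
* **Nearest-centroid subtyping.** The mouse profile is mapped through a
  gene-symbol map onto the centroid signature; distance is `1 − Spearman ρ`
  by default. A bootstrap null (B = 1000) resamples the fold-change values
  onto signature positions without preserving gene pairing; the one-sided
  p-value is `(1 + #{null ≤ observed})/(B + 1)` and assignment minimizes the
  observed/expected relative distance.
* **Copy number.** LRR is corrected by subtracting `c* · (GC − median GC)`
  with `c* = Cov(LRR, GC̃)/Var(GC̃)`, the exact minimizer of the corrected
  variance; the corrected track is segmented by recursive binary splitting
  with a permutation acceptance test, boundary refinement, and SD-undo
  merging; segment means map through cut points `(−1.0, −0.3, 0.3, 0.9)`
  onto states 0 (homozygous loss) … 4 (amplification); only non-normal
  segments strictly longer than 1 Mb are reported, and multi-sample calls
  can be compressed to comparable regions.
* **Cohort contrasts.** Two-sided Wilcoxon rank-sum (exact for small
  tie-free samples, normal approximation with tie/continuity correction
  otherwise) and Spearman cross-platform concordance.

See the methods vignette (`vignettes/glioma-pipeline-methods.Rmd`) for the
assumptions, parameter meanings and design rationale.

## Worked example

```r
library(gliopipe)

## subtype a profile planted to be Proneural-like
cen  <- simulate_centroids(100, seed = 42)
set.seed(1)
prof <- setNames(cen[, "Proneural"] + rnorm(100, 0, 0.5), rownames(cen))
classify_subtype(prof, cen, B = 1000, seed = 7)
#> Nearest-centroid subtype assignment (B = 1000)
#>      subtype observed expected relative  p_value significant
#>    Proneural  0.09138   1.0052  0.09091 0.000999        TRUE
#>       Neural  0.96568   1.0050  0.96088 0.359640       FALSE
#>    Classical  1.15825   0.9965  1.16226 0.947053       FALSE
#>  Mesenchymal  0.99192   0.9997  0.99221 0.459540       FALSE
#> assigned subtype: Proneural
```

The planted subtype sits at ~9% of its expected null distance (p = 1/1001,
the add-one floor); the other three are indistinguishable from their nulls.

```r
## recover the GC-wave coefficient on a wave-plus-noise track
flat <- simulate_marker_track(c(chr1 = 100e6), 50000, NULL,
                              wave_coefficient = 0.5, noise_sd = 0.15,
                              seed = 3)
fit_waviness(flat$track)$fit
#>    scope coefficient gc_median variance_before variance_after
#> 1 genome       0.557     0.494          0.0265         0.0232

## call an injected 5 Mb hemizygous loss through the full chain
truth <- data.frame(chrom = "chr1", start = 20e6 + 1, end = 25e6,
                    state = 1L, shift = -0.6)
sim <- simulate_marker_track(c(chr1 = 100e6), 50000, truth,
                             wave_coefficient = 0.5, noise_sd = 0.15,
                             seed = 3)
fw  <- fit_waviness(sim$track)
filter_cnvs(call_states(segment_lrr(fw$track, seed = 4)))
#>   chrom start     end n_markers mean_lrr state
#> 1  chr1 2e+07 2.5e+07       100   -0.506     1

## rank-sum contrast on a cohort with a planted z-score shift
tab <- simulate_cohort(200, effect = 1, mutant_fraction = 0.3, seed = 5)
group_contrast(tab, "mutation_status")
#> rank-sum normal-approx: statistic = 6513, p = 7.047e-10
#>      label   n      median
#>     mutant  60  0.90661021
#>  wild-type 140 -0.03784322
```

The fitted wave coefficient (0.557) recovers the planted 0.5 within the
sampling error of a 2000-marker track; the injected loss is reported at the
exact marker boundaries with the correct state; the planted one-SD z-score
shift is detected with the expected median separation.

A full run (`simulate → normalize → subtype → cnv → cohort`) is one call —
`run_pipeline("all", out_dir = "run1")` — or from the shell:

```sh
Rscript inst/cli/gliopipe.R all --out-dir run1 --seed 1
```

Outputs are TSV/JSON/BED files plus a resolved config and a checksum
manifest; identical config and seed give identical outputs.

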