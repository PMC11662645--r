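---
title: "hetscreen: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hetscreen: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetscreen)
```

## Scope

`hetscreen` re-implements, as a reusable and tested pipeline, the analysis of
colony-array silencing screens that probe heterochromatin function at four
domains of the fission-yeast genome (CEN, MAT, SUBTEL, TEL) with a `ura4+`
reporter and a dual −URA / +FOA selection readout, together with the
companion analyses: hit calling and its calibration, phenotypic-profile
clustering, protein-complex coherence testing, and single-cell
reporter-state quantification from flow-cytometry exports. Everything
upstream of a colony-size table (image segmentation, robotics) and all
wet-lab assays are out of scope.

## Scoring model

The pipeline order is fixed and pinned by a regression test, because plate
normalization and the log transform do not commute:

1. **Relative growth** `r = selective / non-selective` per colony position.
   A missing or zero colony on either medium gives a missing ratio. No
   pseudocount is used: a zero colony call is almost always a failed pin or
   a segmentation dropout, and inventing growth there would bias hit calling.
2. **Plate-median normalization**: each ratio is divided by the median of
   its own 384-position plate (one plate = one screen × readout × plate ×
   replicate group). This removes multiplicative plate effects such as
   batch-to-batch differences in medium strength. Plates with an undefined
   or zero median are dropped with a warning rather than silently imputed.
3. **log2**, then the **mean over technical replicates** (2 by design, up to
   4 supported) defines the biological-replicate value.
4. **Scale and center** per (screen, readout) dataset, pooled over all
   biological replicates: subtract the dataset median, divide by the sample
   SD (n−1). Median-centering (not mean-centering) keeps the bulk of
   unperturbed mutants at 0 even with heavy hit tails. Whether the original
   analysis pooled replicates before or after computing the SD is not
   documented anywhere we could verify; pooling is this package's choice and
   is the only option implemented — it is what makes the two readouts of one
   screen addable on a common scale.
5. **Combined FOA/URA score** `S = z(URA) − z(FOA)`. Silencing defects
   de-repress the reporter: better growth without uracil (positive z) and
   FOA toxicity (negative z), so the subtraction aligns both readouts with
   positive = loss of silencing.

**Degenerate datasets.** `scale_and_center()` errors when the dataset SD is
zero — for real data that always indicates an upstream bug. The pipeline
wrapper `score_screens()` instead maps a fully degenerate dataset to
centred (all-zero) values with a warning, so that noise-free simulations
flow through end to end; the strict contract lives in the low-level
function, the forgiving behaviour in the orchestration layer.

## Hit calling

Per gene and screen, a one-sample Student's t-test of the biological-replicate
combined scores against 0, with the **median** combined score as the effect
size (the t-test uses the mean; both are reported). Hits require raw
`P < 0.05` and median > +2.5 (MAT, SUBTEL, TEL) or +3 (CEN) for silencing,
median < −2 / −3 for anti-silencing. Three deliberate properties:

- The thresholds are asymmetric (+2.5 vs −2) and per-screen; they are
  preserved exactly as published, not symmetrized.
- No multiple-testing correction is applied to the calls (matching the
  original design, which controls false positives through the joint
  p-and-effect rule); a Benjamini–Hochberg column is emitted for information.
- Genes with fewer than 2 replicates are *untestable* (`direction = NA`),
  not non-hits; the minimum n = 2 is this package's documented choice.

Degenerate spread: SD = 0 with nonzero mean gives p = 0 with a `degenerate`
flag (the data are maximally reproducible, but the t statistic is undefined);
SD = 0 with mean 0 gives p = 1.

Calibration helpers follow the published procedure: recall restricted to
gold-standard genes actually tested (gold lists are flat files compiled from
GO/FYPO terms — GO:0000792, GO:0000781, GO:0033696, FYPO:0004604 — no live
ontology queries), and precision as the fraction of validated hits with
reporter transcript fold-change strictly above 1.5. `fisher_enrichment()`
delegates to `stats::fisher.test` (two-sided, conditional-MLE odds ratio);
the test suite checks it against an independent exhaustive hypergeometric
enumeration. Note that for a perfectly overlapping 10/10 set in a universe
of 20 the two-sided p is `2/C(20,10)`, not the single-tail point mass — both
tails are equally extreme.

## Profile clustering

Features are the 8 per-gene **median log2 relative-growth** values
(4 screens × 2 readouts) — the heatmap quantity — not combined scores.
SUBTEL and TEL columns are half-weighted, implemented by scaling the values
(halving a column quarters its squared-distance contribution; verified
against a weighted-distance oracle). Genes with any missing feature are
excluded before clustering and reported.

Consensus k-means: `n_runs` rounds of `stats::kmeans` from distinct
sub-seeds (each round uses `nstart = 5`; single-start Hartigan–Wong lands in
split/merge local optima often enough to corrupt a consensus even at large
separation), labels aligned to the first round by greedy maximal-overlap
matching, genes assigned by majority label with a support fraction, ties
broken toward the lower cluster id. `k` is a required user parameter — the
original choice of 7 per direction was made on biological grounds and no
automatic selection is offered. Rare ambiguous genes were manually resolved
in the original analysis; that remains a human step (an override file on the
assignment table), not an algorithm.

Within each cluster, genes are ordered by the leaf order of agglomerative
hierarchical clustering on Euclidean distance. The linkage was not recorded
in the original analysis; the default is complete linkage, configurable
(`average`, `single`, `ward.D2`). The same weighted matrix feeds both
k-means and the hierarchical step. Leaf order is defined only up to subtree
flips, so tests assert flip-invariant facts (first-merged pairs adjacent,
outliers at a boundary), not one specific orientation.

## Complex coherence

A gene's phenotypic profile is its 4-vector of mean combined scores per
screen (fixed order CEN, MAT, SUBTEL, TEL); an 8-dimensional
screen × readout mode exists because a Pearson correlation over 4 points is
coarse, and the mode is recorded in outputs. Pairwise Pearson correlations
are classified within- vs between-complex over a one-complex-per-gene
membership table (overlaps are rejected, not resolved silently).

The permutation test asks whether same-complex subunits have more similar
profiles than different-complex subunits. Statistic: mean within-pair r
minus mean between-pair r (the original analysis did not name one; the
fraction-above-threshold difference is available as an alternative). Null:
permute the gene → complex assignment among annotated genes, preserving
complex sizes — the unannotated background is not drawn into the null, which
keeps the test about the structure *within* the annotated set. One-sided
(within > between), add-one estimator `p = (1 + k)/(1 + n_perm)`, so p is
never 0 and never below `1/(n_perm+1)`. On tiny inputs (≤ 8 genes with no
more distinct arrangements than `n_perm`) the null is enumerated
exhaustively and flagged. For the default statistic the Monte-Carlo loop
only recomputes the within-pair sum (the pair counts and the total pair sum
are permutation-invariant, and the statistic is monotone in that sum), which
makes 10^4 permutations on a 70-gene set take well under a second.

## Flow-cytometry reporter states

Per cell, green (nucleation-site) and orange (distal-sensor) signals are
divided by the red euchromatic control — this cancels extrinsic cell-to-cell
variation exactly, which is why downstream results are invariant to any
global instrument gain (tested end to end). Gating uses two controls: the
99.5th percentile of the red-normalized signals in a red-only strain sets
the color-negative cutoff (the percentile is this package's
operationalization of an unspecified original cutoff; configurable), and the
mean red-normalized signal of color-positive cells in the
no-heterochromatin control sets the per-channel "max" (mean by default,
median available — the original estimator is unspecified). Analysis cells
below both cutoffs are excluded as reporter-loss events.

Scaled signals (`value / max`, clipped at 1.5 — values above the control
maximum are biologically meaningless overshoot and would distort densities)
are summarized as OFF (< 0.1), intermediate, ON (≥ 0.8) fractions on the
orange axis. These bounds are an explicit convention of this package: the
original work presents densities and describes the states qualitatively.
The density output uses `stats::density` with Silverman's rule-of-thumb
bandwidth; the "hexbin" is a rectangular 2D histogram over
[0, ceiling]² — hexagonal tiling is a plotting concern, not an analysis one.

## Synthetic data: the stated world

The generator inverts the scoring model, so that with zero noise the
pipeline recovers planted effects exactly (proportionally — see below):

- NS colony size ~ lognormal(log 400, 0.1) in arbitrary area units;
- selective size = NS × plate_effect × 2^(signal + ε) with
  signal = +α·effect on URA and −β·effect on FOA (α = β = 0.5),
  ε ~ N(0, noise_sd = 0.5 log2 units), plate_effect = 2^N(0, 0.25) shared
  per selective plate. Applying plate effects to selective plates only is
  deliberate: relative growth does *not* cancel them, so they are exactly
  the stress case plate-median normalization must handle;
- defaults: 2,000 genes, 5% silencing class (+4), 5% anti-silencing (−4),
  biological replicates CEN 8 / MAT 7 / SUBTEL 3 / TEL 6, 2 technical
  replicates — the real screen's design;
- effects are specified on the combined-score scale *pre*-standardization.
  Because scaling divides by the realized screen SD, recovered effects are
  proportional to planted ones, not equal; tests therefore assert ranks,
  proportionality and threshold behaviour, never raw equality.

What it does not emulate: spatial plate gradients and neighbour effects
(the real analysis addresses position effects only through relative growth),
edge-row artefacts, library strain dropouts, linkage between neighbouring
genes, or mis-annotation structure. A green recovery test therefore
establishes the statistical machinery, not robustness to those artefacts.

Complex profiles: members share a latent standard-normal 4-vector with
weight √ρ plus independent noise √(1−ρ), giving expected within-pair
Pearson r ≈ ρ (slightly below, by the small-sample bias of r over 4 points —
the calibration test allows ±0.05). Cell populations: OFF/ON mixture on the
red-normalized scale (OFF 0.08, ON 1.0 = the control max) with lognormal
intrinsic noise cv = 0.12. That cv was chosen once, a priori, from
self-consistency: with the ON component sitting at the control maximum and
the ON boundary at 0.8 of max, the ON state must have ≲ 12% ratio noise for
threshold classification to recover mixture fractions to ±0.02 — which is
also what per-cell red normalization realistically leaves (it removes the
extrinsic part of the noise). The red-only control's apparent green/orange
background is 0.005 of red, an order of magnitude below the OFF state's
residual expression, so color-negative gating and the OFF state remain
distinguishable.

## Determinism

Every stochastic component takes an explicit seed, derives sub-seeds below
2^31, and restores the caller's RNG state on exit (so drawing fresh seeds in
a loop around these functions behaves as expected). The pipeline manifest
records the package version, seed, a content hash of the config, and an md5
per output file; identical config + seed give byte-identical tables.

## Known limitations

- Replication of the published screen's headline numbers requires the
  article's supplementary per-replicate score tables; the harness for them
  ships (and deliberately fails) in the acceptance tests, but the tables
  themselves cannot be redistributed.
- XLSX supplementary files must be exported to TSV/CSV before
  `read_score_table()` can ingest them; no binary spreadsheet reader is
  bundled.
- The permutation test's fast path applies to the mean-difference statistic
  only; the threshold-fraction statistic uses the generic (slower) loop.
- `k` selection, GO-based cluster naming, and resolution of ambiguous
  cluster assignments are human steps by design.
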