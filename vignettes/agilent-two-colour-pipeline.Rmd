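---
title: "Processing two-colour expression arrays: methods and modelling choices"
author: "AgiPipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing two-colour expression arrays: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

AgiPipe processes two-colour (Cy3/Cy5) expression microarrays produced in
a *reference design*: every array hybridises the same reference RNA in
the Cy3 (green) channel and an experimental sample in the Cy5 (red)
channel. The package covers the post-scanner stages: parsing Feature
Extraction (FE) files, log2 transformation and replicate collapsing,
normalization of each array to the per-probe mean reference, variance and
normality quality control, expressed/not-expressed calling against
negative-control background, and classical multidimensional scaling (MDS)
of the arrays. A synthetic-data generator with known truth tables
supports validation of every stage.

This vignette records the statistical model, the default parameter
values, and the numerical conventions, so that results are interpretable
and reproducible without reading the source.

# Data model

## FE files

An FE file is a tab-delimited stanza format. The line whose first token
is `FEATURES` names the columns; each subsequent `DATA` line is one
spotted feature. AgiPipe reads columns by *name*, not position, and
requires `ProbeName`, `ControlType`, `gMedianSignal` (Cy3) and
`rMedianSignal` (Cy5). Rows with missing or non-positive signals are
dropped and counted in a parse report; a missing required column is
fatal, naming the column.

## Scales and transforms

All statistics operate on `log2` signal. The raw scanner scale is
multiplicative — the per-probe SD grows roughly linearly with the mean —
so the log2 transform is the first variance-stabilising step
(`sdVsMean()` quantifies the residual dependence before and after).
Non-positive raw signals cannot be log-transformed and are treated as
parse failures, never silently clamped.

## Replicates and collapsing

A probe sequence may occupy several features. `collapseReplicates()`
averages the log2 values of all features of one probe within an array and
records the within-probe SD; the negative-control probe (by default
`(-)3xSLv1`) is collapsed the same way but flagged so downstream stages
can exclude or target it.

# Normalization to the mean reference

Because every array carries the same reference sample in Cy3, the
per-probe mean of the Cy3 channel over arrays (`meanReference()`, n >= 2
arrays) estimates the "true" reference signal. Each array is then
corrected towards that template; the same model fitted on an array's Cy3
channel is applied to its Cy5 channel, since both share the array's
hybridisation and scanning biases.

* **Linear**: ordinary least squares of the array on the template;
  correction `y - ((a + b x) - x)`.
* **Segmented LOESS** (default): a tricube-weighted local-linear smoother
  with bandwidth `range(x) / segments` (default `segments = 10`),
  evaluated at 101 grid points and linearly interpolated (constant
  extrapolation beyond the grid). If a neighbourhood holds fewer than 10
  points it is widened by 1.5x with a warning rather than failing — log2
  signal is dense around the background and expressed modes but sparse
  between and above them.
* **Quantile**: each array's values are replaced by the mean of the
  order statistics across arrays (ties receive the average), the classic
  rank-based scheme. Provided for comparison; it equalises entire
  distributions rather than correcting each array towards the reference
  template, and flattens genuine distributional differences, which
  inflates apparent reproducibility without improving per-probe accuracy.

`leaveOneOut = TRUE` excludes the array being corrected from its own
template, removing the self-correlation otherwise introduced at small n.

# Variance model and the corrected SD of the ratio

For probe i with per-channel across-array SDs `sdE` (Cy5) and `sdR`
(Cy3) and between-channel covariance `cov`, the SD of the per-probe
log-ratio (difference of log2 signals) is

    sd_diff = sqrt(sdE^2 + sdR^2 - 2 * cov)        (Eq 1)

implemented by `sdOfDifference()`. Taking ratios is only beneficial when
`cov` is large relative to the channel variances; reporting the
covariance makes that trade-off explicit. All SDs and covariances are
sample statistics with the n - 1 denominator. `sdOfDifference()` rejects
`cov^2 > sdE^2 * sdR^2` (impossible for a genuine covariance) and clamps
a negative radicand within 1e-8 to zero with a warning. When Eq 1 is
applied to probe-*averaged* summary statistics (`channelStats()`
summary), the radicand can be slightly negative for near-perfectly
correlated channels because averaging does not commute with products;
the summary value clamps at zero, while the per-probe primitive stays
strict.

`normalityScreen()` applies the Shapiro-Wilk test per probe and reports
the fraction with p > 0.05 (plus a Benjamini-Hochberg-adjusted
companion); on Gaussian data this fraction is 0.95 by construction, so
deviations measure distributional distortion introduced by processing.

# Background and expressed/not-expressed calling

The negative-control probe has no target and estimates the background
hybridisation level. `fitBackground()` takes the mean (default) or
median of its log2 signals per array, plus a pooled value.
`callExpressed()` counts probes *strictly above* background + threshold
— a probe exactly at background is "off" — over an ascending threshold
grid (default 0 to 1 by 0.1), giving a monotone non-increasing call
curve. `channelInterference()` quantifies leakage of the experimental
signal into the reference channel: within bins of the Cy5
stimulation-response difference, the correlation and OLS slope of the
matched Cy3 difference, plus the same statistics over the top-N (default
50) largest Cy5 differences.

# Classical MDS

`distanceMatrix()` computes Euclidean distances between arrays over
probes (controls excluded by default). `classicalMDS()` double-centres
the squared distances (B = -1/2 J D^2 J), eigendecomposes, and scales
eigenvectors by the square roots of the positive eigenvalues. Signs are
fixed by making each dimension's largest-magnitude loading positive, so
output is deterministic. Goodness of fit for k dimensions is

    P_k = sum(lambda_1..k, clamped at 0) / sum(all lambda, clamped at 0)   (Eq 2)

Negative eigenvalues (non-Euclidean noise) are clamped to zero in both
sums; double-centring forces at least one zero eigenvalue, so the
denominator effectively has n - 1 terms and `P_{n-1} = 1`.
`selectDimensions()` returns the smallest k with `P_k >= 0.8` (the
default cutoff). Per-dimension strip plots add small seeded horizontal
jitter purely to reduce overplotting.

# The synthetic generator

`simConfig()` / `generateDataset()` produce FE files with a known truth
table. The model for a probe with true log2 mean `mu` on array a is

    signal = bias_a(mu') + noise,
    bias_a(x) = x + offset_a + (slope_a - 1) (x - center) + curv_a (x - center)^2

where `mu'` is `mu` plus any class-signature or stimulation effect in
the Cy5 channel. The bias acts on the *true level* and noise is added
afterwards, so array biases shift probes without rescaling their noise;
this makes closed-form oracles (per-probe SD, binomial call counts)
exact. Defaults are desk-scale study conditions for a 4 x 44K human
whole-genome design:

| Parameter | Default | Meaning |
|---|---|---|
| `nProbes` | 2000 (41001 at `fullScale`) | unique probes |
| `nReplicateProbes` x `replicateCount` | 263 x 10 | replicated probes |
| `negativeControlCount` | 153 | copies of `(-)3xSLv1` |
| `nArrays` | 10 | arrays |
| `meanLog2`, `probeSd` | 8.5, 2.0 | expressed-probe mean distribution |
| `noiseSdCy3`, `noiseSdCy5`, `channelCov` | 0.24, 0.52, 0.09 | genewise noise (log2) |
| `intraSdCy3`, `intraSdCy5`, `intraCov` | 0.16, 0.20, 0.02 | within-array replicate noise |
| `offsetRange`, `slopeRange`, `curvatureRange` | 0.5, 0.9–1.1, 0.02 | per-array bias draws |
| `expressedFraction` | 0.70 | truly expressed probes |
| `backgroundLog2`, `backgroundSd` | log2(60), 0.25 | background level and spread |

Expressed probe means are drawn truncated-normal at least 1.2 log2 units
above background, so "expressed" is a well-separated truth label;
non-expressed probes and negative controls fluctuate around the
(bias-shifted) background. Channel noise is drawn jointly with the
configured covariance via a two-variable Cholesky factorisation that
tolerates zero SDs, so noiseless configurations are exact. Identical
configuration and seed give byte-identical files (values are written
with 12 significant digits).

`generateOffDomainSample()` emulates hybridising RNA from a distantly
related organism: all probes sit at background except a small elevated
fraction (default 2% at +1 log2). With the default background SD of
0.25, the expected fraction of probes more than 0.5 log2 above
background is about 4%, below the 5% calibration bound used in the
tests.

The generator emulates the *statistical* structure (noise, covariance,
replicates, biases, background, class signatures); it does not emulate
spatial artefacts, dye-swap designs, saturation, or probe-sequence
effects.

# Pipeline and provenance

`runPipeline()` chains the stages from a list or YAML config (simulate
block or an input FE directory; method; thresholds; MDS cutoff; seed).
Every output carries a provenance header with a 32-bit FNV-1a hash of
the analysis-relevant configuration (the output directory is excluded)
and the seed; the run log contains no timestamps, so a rerun with the
same config and seed is byte-identical. Matrices are written with 17
significant digits (`%.17g`), enough to round-trip doubles exactly.

# Limitations

* Normalization assumes the reference channel is comparable across
  arrays; it cannot correct spatially structured artefacts.
* The Shapiro-Wilk screen needs 3 to 5000 values per probe.
* Classical (metric) MDS only; non-metric variants and identifying which
  genes drive each dimension are out of scope.
* The generator's truth is additive on the log2 scale; it does not model
  intensity-dependent covariance.
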