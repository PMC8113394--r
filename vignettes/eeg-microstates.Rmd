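---
title: "Microstate segmentation of resting EEG: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate segmentation of resting EEG: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegmicrostates)
```

## The model

Resting EEG topography does not drift continuously: it lingers in one of a
small number of quasi-stable spatial configurations for tens of
milliseconds and then switches abruptly. The package models a recording as
a hidden semi-Markov sequence of `q` template maps. The observable at
sample `t` is the average-referenced potential vector `v(t)` over `K`
electrodes; its spatial standard deviation is the global field power (GFP).
Two maps are compared by their spatial Pearson correlation across
electrodes with polarity disregarded — equivalently by global map
dissimilarity, `GMD^2 = 2(1 - |corr|)` — because cortical generators
reverse polarity within an oscillatory cycle without changing
configuration.

Fitting proceeds in two stages. First, the maps at GFP peaks (where
signal-to-noise is maximal) are clustered by the Atomize–Agglomerate
Hierarchical Clustering: all maps start as singleton clusters, and the
cluster with the smallest summed GEV contribution is repeatedly dissolved,
each member moving to the remaining cluster of highest polarity-invariant
correlation. A cluster's template is the dominant eigenvector of the sum of
its members' outer products `v v'`; this handles polarity exactly (the
eigenvector is sign-indifferent) and weights members by their squared
amplitude, so low-GFP, noise-dominated maps barely steer a template. The
sign-aligned arithmetic mean was rejected because it depends on the order
in which signs are resolved. Second, every sample of the filtered recording
— not only the peaks — is backfitted to the template of highest
polarity-invariant correlation, and the temporal parameters are read off
the label sequence.

The number of classes is selected by the predictive cross-validation
criterion `CV(q) = sigma2_hat * ((K-1)/(K-1-q))^2`, where `sigma2_hat` is
the mean residual variance of the maps about their assigned templates. CV
falls while added templates explain real structure and rises once they fit
noise; the minimizer is chosen, with ties broken toward smaller `q`
(parsimony). Plain AAHC can occasionally fragment one true class into two
high-quality sub-clusters while a genuinely distinct but weaker class holds
the smallest GEV contribution; stepping down then removes the wrong
cluster, and CV prefers the larger `q` where all true classes are intact.
On the default synthetic conditions this affects roughly one run in ten;
it is a property of the algorithm rather than of the implementation, and
the cross-validated choice remains the honest summary of the hierarchy.

## Tunable parameters

* `bandpass_low_hz` / `bandpass_high_hz` (Hz; 2 / 20): analysis band. The
  filter is a 4th-order Butterworth applied forward–backward
  (`signal::filtfilt`), i.e. zero-phase, with stopband attenuation of at
  least 20 dB one octave outside the band. Filtering precedes epoching so
  filter transients never sit at epoch boundaries.
* `epoch_length_ms` (ms; 2000): epoch window. Segmentation is contiguous
  from the first sample; a trailing partial epoch is discarded.
* `q_range` (2..8): CV search range; must stay within `[2, K-2]` or the CV
  penalty is undefined.
* `polarity_invariant` (TRUE): disregard map polarity in matching —
  the microstate convention.
* `smoothing_min_ms` (ms; 0): minimum segment length enforced after
  backfitting. Off by default: the headline temporal parameters are defined
  on the raw label sequence, and smoothing is provided only because segment
  statistics are sensitive to single-sample flicker. When enabled, samples
  of a short run move to the neighboring run's class with the higher
  per-sample similarity, iterated to a fixed point.
* `alpha_family` / `n_comparisons` (0.05 / 4): the per-comparison
  Bonferroni threshold, 0.0125 by default; a secondary flag marks the
  study-wise 0.01 level.

## Temporal parameters and conventions

Segments are maximal same-label runs within an epoch. Runs touching an
epoch's first or last sample are truncated by the window, so they are
excluded from mean duration and occurrence (otherwise durations would be
biased downward) but still count toward coverage, which is a pure
time-share. All statistics pool totals across epochs rather than averaging
per-epoch means, so epochs with more segments weigh more. On sequences with
no truncated runs the identity `coverage = occurrence * duration / 10`
(coverage in %, occurrence in 1/s, duration in ms) holds exactly and is
asserted in the tests. Transitions are counted between consecutive runs of
different classes within an epoch — never across epoch boundaries, and an
unassigned stretch (zero GFP) breaks adjacency. Rows of the transition
matrix are conditional probabilities; rows with no outgoing transitions are
flagged rather than silently normalized. The observed conditional
probabilities are reported as-is; a correction for what would be expected
under independence of base rates is a possible extension but is not
applied, since the correlation analysis consumes the observed
probabilities.

## Canonical labeling

A fitted four-map set is labeled MS1–MS4 by matching against built-in
idealized normative topographies evaluated on the montage geometry: two
mirrored diagonal dipolar fields (right-anterior/left-posterior and its
mirror), an anterior–posterior midline field, and a fronto-central focal
map. The assignment maximizes total polarity-invariant similarity over all
24 permutations (exhaustive, so globally optimal). With `q != 4` the
templates keep the label `other` and a warning is raised. The idealized
fields are smooth Gaussians on schematic 2-D head coordinates; they are a
labeling aid, not a claim about source geometry.

## What the synthetic generator emulates — and what it does not

`eeg_generator_spec()` encodes the assumed data-generating process:
four orthonormalized canonical maps on the 19-channel 10–20 montage, a
semi-Markov label sequence with geometric (memoryless) dwell of mean 80 ms
(a gamma option gives more realistic unimodal duration histograms), an
alpha-band carrier at 10 Hz (eyes-closed resting EEG is alpha-dominated,
and GFP then peaks twice per cycle), and spatially correlated noise with a
1/f spectrum mixed through a distance-based covariance
(`exp(-d^2 / 2l^2)`, l = 0.6 head radii). The default montage is the
19-channel set to keep simulation and tests fast; a synthetic ring montage
supports arbitrary channel counts, including 64 channels as used in denser
caps. The default signal-to-noise ratio — mean template-signal GFP over
mean noise GFP — is 0.9, chosen once so that the four-class solution on
default recordings explains close to 79% of the GFP-weighted variance, the
level reported for real resting data of this kind; at that setting template
recovery is still essentially exact (spatial correlation > 0.99).

The generator does not attempt biophysical realism: no head model, no
dipole sources, no electrode drift, no residual ocular or muscle artifacts
(artifact correction is an upstream contract of the pipeline). Passing
recovery tests on synthetic data therefore demonstrates the correctness and
calibration of the estimation chain, not robustness to every failure mode
of real recordings.

A consequence of the oscillatory carrier worth knowing: near carrier
zero-crossings the instantaneous map is noise-dominated, so raw backfit
labels flicker there and the estimated mean durations sit well below the
generating dwell time even though coverages, transition
structure and templates are recovered faithfully. This mirrors real data,
where reported durations depend on the labeling convention; recovery of the
generating dwell is asserted on the label sequences themselves, where it is
unbiased.

`cohort_generator_spec()` draws MPATS item responses from four correlated
latent factors (one loading per subscale; items discretized to Likert 1–5
by equal-probability thresholds, putting the mean total at 48). Loadings
and the uniform inter-factor correlation are calibrated by
`calibrate_cohort_loadings()` — target alpha to required inter-item
correlation in closed form, divided by the discretization attenuation
(0.897, fixed once from a large-n simulation of the full item model) — so
that population reliabilities match the published sample values: total
0.87, subscales 0.80 / 0.70 / 0.82 / 0.40. The item partition
(6/4/3/3 across withdrawal symptoms, salience behavior, social comfort,
mood changes) follows the published scale structure. Microstate parameters
are drawn with realistic marginals (durations around 72–85 ms, occurrences
around 3/s, coverages around 25%), independent of the scores unless a
linkage `(score, parameter, r)` is requested, in which case the parameter
loads on the standardized observed score at population correlation `r`.
Ages are rounded normals around 20 (range 17–26), sex is Bernoulli(0.5);
both are pure nuisance covariates with no built-in effects, which is
exactly what the covariate-adjustment machinery should be invariant to.

## Statistical machinery

Scores and microstate parameters are residualized on an intercept, age and
sex by OLS before correlation; this equals the partial correlation given
those covariates (asserted against the precision-matrix closed form).
Each residualized variable passes a normality gate: Shapiro–Wilk p > 0.05
is `normal`; otherwise |skewness| < 1 and |excess kurtosis| < 1 is
`approximately_normal` and left untransformed; otherwise the rank-based
inverse-normal (Blom) transform is applied. This mirrors the common
practice of treating mildly non-normal psychometric sums as normal while
still taming genuinely skewed quantities. p-values use the exact
t-transform `t = r sqrt(n-2) / sqrt(1-r^2)` with `n-2` degrees of freedom,
two-sided. The correlation table crosses the five scale scores with all 24
microstate parameters, reports full-precision p, and flags both the
Bonferroni threshold (0.0125) and the 0.01 study-wise level, since both
conventions appear in practice.

## Numerical choices and degenerate inputs

* Template rows are centered and unit-L2-normalized on construction;
  correlation against unit-norm templates reduces to a dot product.
* Zero-GFP samples cannot be correlated with anything; they are labeled 0
  (unassigned), excluded from all statistics, and break run adjacency.
  Zero-GFP maps in the clustering input are an error, not a warning.
* Backfit ties break toward the lower class index, deterministically.
* The CV selection breaks ties toward smaller q.
* EDF support is a minimal continuous 16-bit reader/writer: round-trips
  are exact to the quantization step of the stored physical range; the
  plain-text matrix dialect (CSV + YAML sidecar) round-trips to ~1e-12 and
  is the lossless interchange format. Readers reject, rather than repair,
  channel-count mismatches. Unknown YAML config keys are errors so a typo
  cannot silently fall back to a default.
* All generators are bit-reproducible from their seed.

## Problem sizes

The test-suite simulations are sized for quick, repeated runs: recording
lengths of 8–20 s (15 s for the cluster-number replicates, 20 replicates),
600 s label-only sequences where ten thousand transitions are needed, 500
replicate cohorts of n = 335 for the type-I calibration of the full
correlation table, and 10–20 subject demos. The acceptance script uses the
full default recording length (60 s, 10 recordings) and 20 cohorts of
n = 335. These sizes are the package's own validation choices; all
tolerances scale with the law-of-large-numbers error of the corresponding
size and are stated next to each assertion.

## Known limitations

* Plain AAHC's occasional class fragmentation (above) means CV can report
  5–6 classes on data generated with 4; a modified k-means backend for
  cross-checking solutions is a natural extension.
* Duration estimates from raw (unsmoothed) backfit labels are
  convention-dependent and biased short under oscillatory carriers.
* The EDF reader covers the continuous, uniform-rate subset of the format
  used here; EDF+ annotations and discontinuous records are out of scope,
  as are proprietary acquisition formats — convert upstream.
* Group templates assume a shared montage across subjects; no spatial
  interpolation between montages is attempted.
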