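# eegmicrostates

Resting-state EEG microstate analysis in R: topographic segmentation of
multichannel EEG into the four canonical quasi-stable classes (MS1–MS4,
a.k.a. A–D), extraction of their temporal parameters, and covariate-adjusted
correlation of those parameters with psychometric trait scores such as the
16-item Mobile Phone Addiction Tendency Scale (MPATS). It is written for
cognitive/clinical neurophysiology groups who want the full analysis chain —
and a synthetic ground-truth generator to validate it — in one auditable
package.

## The method

A resting EEG recording is band-pass filtered (2–20 Hz, zero-phase 4th-order
Butterworth), average re-referenced and cut into 2000 ms epochs. The global
field power,

    GFP(t) = sqrt( (1/K) * sum_k ( v_k(t) − v̄(t) )² ),

is the spatial standard deviation of the average-referenced map `v(t)` over
the `K` electrodes. Topographies at GFP peaks (maximal signal-to-noise) are
clustered with the Atomize–Agglomerate Hierarchical Clustering (AAHC):
every map starts as its own cluster, and the cluster contributing least
global explained variance

    GEV = Σ_t ( GFP(t) · corr(v(t), T_L(t)) )² / Σ_t GFP(t)²

is repeatedly dissolved, its members reassigned by polarity-invariant
spatial correlation (global map dissimilarity, `GMD² = 2(1 − corr)`). The
number of classes is chosen by the predictive cross-validation criterion

    CV(q) = σ̂² · ( (K−1) / (K−1−q) )²,

minimized over q = 2..8. The four winning template maps are labeled
MS1–MS4 against built-in normative topographies, every sample is backfitted
to its best template, and the per-class mean duration (ms), occurrence
(1/s), coverage (%) and run-to-run transition probabilities are computed.
Trait–parameter association uses Pearson correlation on residuals (age and
sex partialled out), with a Shapiro–Wilk/skewness–kurtosis normality gate,
rank-based inverse-normal transform where needed, and Bonferroni control
(0.05/4 = 0.0125 per comparison).

Because raw study data of this kind are rarely shareable, the package ships
generators with known ground truth: semi-Markov microstate sequences
rendered into alpha-carrier EEG with spatially correlated 1/f noise, and
latent-factor MPATS cohorts calibrated to the published reliabilities
(total-scale Cronbach's alpha 0.87), with configurable trait–parameter
linkage.

## Worked example

```r
library(eegmicrostates)
set.seed(20)
spec <- eeg_generator_spec(duration_s = 30, seed = 20)  # 4 classes, 80 ms dwell
sim  <- simulate_recording(spec)
fit  <- microstates(sim$recording)                      # CV selects q
fit
#> Microstate segmentation
#>   4 classes (MS1, MS2, MS3, MS4), 15 epochs x 1000 samples @ 500 Hz
#>   GEV: 0.799 (all samples), 0.874 (GFP peaks)
#>   q selected by CV over {2, 3, 4, 5, 6, 7, 8}
fit$diagnostics
#> <cluster_diagnostics>
#>           2       3       4      5       6       7       8
#> CV  64.4100 43.1300 22.2600 24.920 27.7000 31.4100 36.2100
#> GEV  0.5224  0.7189  0.8736  0.878  0.8844  0.8899  0.8951
#> selected q = 4
round(abs(coef(fit) %*% t(sim$templates$maps)), 3)      # template recovery
#>       MS1   MS2   MS3   MS4
#> MS1 0.999 0.037 0.018 0.031
#> MS2 0.043 0.998 0.036 0.021
#> MS3 0.023 0.049 0.998 0.010
#> MS4 0.020 0.042 0.022 0.999
```

The CV criterion bottoms out at the generating class count (q = 4), the
explained variance of the four-class backfit is ~0.80, and each fitted map
matches its generating template at spatial correlation ≥ 0.998. The fit
object also carries `fit$metrics` (durations, occurrences, coverages,
transition matrix) and supports `summary()`, `predict()` (backfit new data),
`simulate()` (regenerate EEG from the fitted model), `residuals()` and
`plot()`. `run_demo()` runs a whole multi-subject pipeline —
subject clustering, group templates, backfitting, metrics and the
trait-correlation table — on synthetic data and reports ground-truth
recovery; `run_pipeline()` does the same for real EDF/CSV recordings and a
cohort table.

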