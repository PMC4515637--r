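---
title: "Classifying neuron subtypes from inter-spike-interval statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying neuron subtypes from inter-spike-interval statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Extracellular recordings yield spike timestamps for tens of units per
session, and anatomically homogeneous populations (hippocampal CA1
pyramidal cells, midbrain dopaminergic neurons) often hide functionally
distinct subtypes. `isica` classifies units from the statistics of their
inter-spike intervals (ISIs) alone, in four stages: per-unit feature
extraction, a pre-clustering normality screen, cosine-distance k-means with
many random restarts, and jump-method selection of the cluster count,
followed by Monte-Carlo validation of the result against a homogeneous
Gaussian null.

## Stage 1 — ISI features

For each unit, restricted to one brain state (quiet awake, slow-wave sleep,
anesthesia), the package computes:

* **Gamma shape `k` and scale `theta`** by maximum likelihood on the raw
  ISIs. The gamma family indexes spike regularity: `k = 1` is the
  exponential/Poisson case, `k < 1` means excess short-and-long intervals
  (bursty firing), `k -> Inf` means clockwork regularity. The shape solves
  the profile-likelihood equation `log(k) - digamma(k) = log(mean ISI) -
  mean(log ISI)` by Newton iteration from the method-of-moments start
  `k0 = mean^2 / var` (tolerance `1e-10` on `k`, 200-iteration cap; in
  practice it converges in under ten). Units with 250 or fewer ISIs are
  not fitted — small samples bias the shape — and are reported as excluded
  rather than silently dropped. Fitting uses raw intervals, not histogram
  counts: the likelihood of the intervals is the quantity the histogram
  approximates, so binning is for display only.
* **Coefficient of variation** `cv = sd(ISI) / mean(ISI)` with the sample
  (n−1) standard deviation: 1 for a Poisson process, below 1 for regular
  firing, above 1 for irregular firing. For a pure gamma renewal process
  `cv = 1/sqrt(k)` exactly; real neurons sit off that curve, which is why
  the pair `(k, cv)` carries more information than either alone.
* **Burst index**: the fraction of ISIs strictly shorter than 10 ms (the
  usual burst definition; the 10 ms boundary itself does not count).
* **Mean firing rate** over the state's total epoch time.

Epochs are half-open `[start, end)` intervals, and ISIs that straddle an
epoch boundary are masked out, so renewal statistics never include
artificial gap intervals. Both `k` and `cv` are invariant to rescaling all
ISIs by a positive constant (`theta` scales linearly), and both are
empirically independent of firing rate on rate-varying, shape-fixed
populations — they measure pattern, not intensity.

## Stage 2 — pre-clustering screen

Before clustering, each feature column is tested for normality with the
D'Agostino–Pearson omnibus test (`K2 = Z_skew^2 + Z_kurt^2` against
chi-square with 2 df; `n >= 20` required). Rejection is treated as evidence
that sub-populations are plausible. The report states only that normality
was rejected — multimodality is one explanation among several — and the
pipeline treats a non-rejection as a gate with an override
(`force_cluster = TRUE`), not a hard stop.

## Stage 3 — cosine k-means

Units are clustered in the raw `(k, cv)` plane under the cosine distance
(one minus the cosine of the angle between feature vectors), with each
centroid the arithmetic mean of its members. Because Lloyd iterations under
this metric depend on the starting centroids, the algorithm restarts 10,000
times (the default budget) from random data points, and empty clusters are
re-seeded at the worst-fit point. The Lloyd core is compiled (Rcpp) so the
full restart budget, and the Monte-Carlo validation below, run at desk
scale.

## Stage 4 — how many clusters?

The jump method transforms the within-cluster dispersion curve `d_K`
(K = 1..k_max) by a negative power, `t_K = d_K^-Y`, and selects the K with
the largest jump `J_K = t_K - t_{K-1}` (`t_0 := 0`, so K = 1 is
selectable; ties break toward smaller K). Two design choices deserve
explanation:

* **What `d_K` is.** The package measures `d_K` as the mean squared
  Euclidean distance per dimension of column-standardized features to
  their cluster means — the Mahalanobis-style dispersion with a diagonal
  covariance that the jump construction assumes — evaluated on the
  partitions produced by cosine k-means, with the best restart at each K
  chosen by that same quantity. The seemingly natural alternative,
  transforming the squared-cosine distortion itself, fails structurally:
  cosine distance is locally already a squared metric and collapses the
  plane onto the unit circle, so its distortion decays like `K^-4` and the
  transformed curve grows without flattening, driving the selection to
  `k_max` on every dataset. A squared-cosine distortion remains available
  via `distortion = "sq_cosine"` for comparison.
* **What `Y` is.** The default is `p/2` (= 1 for the two-dimensional
  `(k, cv)` space), the jump method's standard choice, and it is validated
  on fixtures with genuinely two-dimensional within-cluster scatter. But
  the theory ties `Y` to the *effective* within-cluster dimension. If the
  two features are deterministically coupled — as for pure gamma-renewal
  simulations, where `cv = 1/sqrt(k)` places every unit on one curve —
  within-cluster scatter is one-dimensional, `d_K` decays like `K^-2`, and
  with `Y = 1` the transformed curve again grows superlinearly so that
  large K always wins. For such data `Y = 1/2` (= effective dimension / 2)
  is the correct setting, and the package's population-level tests use it.
  Real recordings, in which bursts, pauses and slow rate modulation
  decouple `cv` from `k`, are the `Y = 1` case. `Y` is exposed everywhere.

A warm start (the previous K's centroids plus the worst-fit point) is added
to each K's restart pool, which keeps the empirical distortion curve
non-increasing at realistic restart budgets.

After selection, `hierarchical_separation()` checks that inter-cluster
cosine distances exceed intra-cluster ones (one-sided t-test on the
pairwise-distance partition, with an average-linkage tree attached for
inspection).

## Validating against a Gaussian null

The cluster index is the within-cluster sum of squared Euclidean distances
to cluster centers divided by the total sum of squared distances to the
grand mean: 1 for a single cluster, smaller for tighter clusterings.
`gaussian_null_pvalue()` draws `n_sim` datasets from a single multivariate
Gaussian with the observed mean and covariance, clusters each with the same
settings (a reduced 50-restart budget — the null needs the distribution of
the index, not global optimality), and reports the add-one estimate
`p = (1 + #{ci_sim <= ci_obs}) / (n_sim + 1)`.

Two notes on this procedure:

* **Direction.** Tight observed clustering gives a *small* observed index,
  so the meaningful tail is the probability that a homogeneous Gaussian
  sample clusters at least as tightly — simulated index *at or below* the
  observed one. The opposite direction would assign large p to exactly the
  datasets that cluster best.
* **Calibration.** Because the null is fitted to the very dataset under
  test, this is a plug-in parametric bootstrap: the simulations inherit the
  data's idiosyncrasies, and under a true Gaussian the p-values are
  under-dispersed (concentrated around 0.5) rather than uniform. We
  verified this property is procedure-inherent, not an implementation
  artifact, by reproducing it with an unrelated Euclidean k-means
  bootstrap. The bias is conservative — the test essentially never produces
  a small p on homogeneous data — so reported significance can be trusted,
  but the p-value is not exactly uniform under the null and should not be
  treated as one.

## Supporting procedures

* **Slow-wave-sleep detection.** The LFP is band-pass filtered (4th-order
  zero-phase Butterworth) in the theta (4–12 Hz) and delta (1–4 Hz) bands;
  per 2 s window (1 s step) the band-power ratio is formed. SWS is
  delta-dominant, so detection thresholds the delta/theta ratio *above*
  `center + 5 * spread`. The center and spread default to median and MAD
  rather than mean and SD: when SWS occupies a sizable fraction of the
  recording, the SWS windows themselves inflate a mean/SD threshold beyond
  every observed value, while robust statistics stay anchored to the
  baseline. Direction, multiplier and statistics are all configurable.
  Epochs must be strictly longer than 5 s. Detection is invariant to
  amplitude rescaling.
* **Power spectra** use non-overlapping 40 s segments (0.025 Hz
  resolution), a rectangular window, bins below 1 Hz discarded as
  noise-sensitive, 0.5 Hz re-binning up to 25 Hz, and normalization to
  percent of total (values sum to 100).
* **Unit screening.** Isolation Distance (squared Mahalanobis distance of
  the n-th nearest noise spike, n = cluster size) and L-ratio (summed
  chi-square tail probabilities of noise spikes over cluster size), with
  the conventional cutoffs Isolation Distance > 15 and L-ratio < 0.7
  applied as strict inequalities. Putative pyramidal cells are rate < 5 Hz
  and width > 300 µs; putative interneurons rate > 10 Hz and width
  < 250 µs; everything else is unclassified.
* **Perievent analysis.** Rates in 0.1 s bins over a ±5 s window are
  z-scored against the pre-event baseline bins. A window is called
  excitatory (inhibitory) when at least 2 consecutive bins exceed z = 2
  (fall below −2); the Early window defaults to (0, 0.5] s and Middle to
  (0.5, 2] s after the event — these bounds are package defaults, fully
  configurable, since no canonical values exist. First-spike latency to
  pulses is averaged over responsive pulses (a spike within 10 ms) with
  SEM over those pulses.

## The synthetic generator

Every stage is testable without recorded data. `simulate_gamma_train()`
draws i.i.d. Gamma ISIs and cumulates them; `simulate_burst_train()` makes
Poisson burst events with fixed (optionally jittered) intra-burst ISIs, so
the burst index has a closed form ((m−1)/m for fixed m-spike bursts) and
`cv` can exceed `1/sqrt(k)`; `simulate_population()` draws per-unit
parameters within subtype ranges using per-unit substreams (hashed from the
root seed and unit index, so adding units never perturbs existing ones);
`simulate_lfp()` schedules band-limited sinusoids in noise; and
`simulate_perievent_train()` thins a homogeneous Poisson process to follow
a perievent rate profile.

What the generator does *not* emulate matters for interpreting green
tests: no spike waveforms, no biophysics, no measurement noise, and —
most importantly — pure renewal trains keep `(k, cv)` on the coupling
curve, so synthetic populations probe the pipeline's bookkeeping,
estimation accuracy and stability, while the jump method's K-selection
accuracy is certified on feature-space fixtures whose within-cluster
scatter is independent 2-D Gaussian, built from the subtype means and SEMs
a real CA1 population produced. Passing tests show the method works under
its assumptions; they cannot show that any particular recording satisfies
them.

Default study conditions mirror the recorded setting the package targets:
two subtypes of 30–36 units, gamma shapes near 0.46 and 0.98, rates of
1.5–4 Hz, sessions of 15–30 minutes per state, and a 10,000-restart
clustering budget. Tests run scaled-down versions of the same conditions
(200 restarts, 500–10,000 null simulations, 100-replicate accuracy
sweeps); the methods' behavior is restart-budget-insensitive at these
problem sizes because the warm start and best-restart selection dominate.

## Numerical choices and degenerate inputs

* Newton iteration for the gamma shape: tolerance `1e-10`, cap 200; any
  non-positive proposal is halved back into the domain.
* Zero-variance ISIs raise an error (the shape is unbounded); `cv` of
  constant ISIs is 0.
* Ties in the jump argmax break toward smaller K (parsimony); a zero
  distortion (exact duplicate units) selects the first K reaching it.
* Cosine distance requires non-zero vectors; zero rows raise an error
  rather than being silently dropped.
* Near-singular covariances in the Gaussian null are ridge-regularized
  (1e-8 of the mean diagonal) with a message.
* Duplicate spike timestamps are collapsed with a warning; negative or
  non-finite timestamps are errors.

## Known limitations

* Features are estimated per state from finite ISI counts; below a few
  hundred ISIs the shape estimate is biased, hence the strict >250 rule.
* The Gaussian-null p-value is conservative (see above), and with the
  default 10,000 simulations its floor is about 1e-4; the million-draw
  setting of the original procedure is available but slow.
* The jump method's `Y` must match the effective within-cluster dimension;
  the package cannot infer it and defaults to `p/2`.
* The SWS criterion is a band-power heuristic; it does not separate REM
  from quiet wakefulness and is not a substitute for polysomnographic
  scoring.
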