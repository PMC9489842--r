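---
title: "Methods: functional-connectivity dynamics in calcium-imaging networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional-connectivity dynamics in calcium-imaging networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fcdyn)
```

This vignette is the package's own account of its science: the model each
stage assumes, the tunable parameters and why their defaults are what they
are, what the synthetic generator does and does not emulate, and the
numerical decisions taken where the method leaves room.

## The pipeline in one paragraph

A recording is a fluorescence intensity matrix F (active neurons × frames)
with sampling period T = 0.1506 s (6.64 Hz; the default geometry is 1877
frames, ~4.7 min). Functional connectivity (FC) between two neurons is the
Pearson correlation of their traces; it is a proxy for communication, not a
causal claim. The static analysis correlates whole traces, thresholds at
|r| > 0.4 into a functional graph, and models the degree distribution. The
dynamic analysis slides a 70-frame window one frame at a time, vectorizes
each window's correlation matrix (strictly-lower triangle, column-major),
and correlates the windows with one another (the FCD matrix). Dimensionality
reduction by ICA yields four "correlation patterns" per network; every
window becomes four regression weights, discretized into signed quartiles
±(1..4); the 4-tuples are meta-states, and nine summary variables describe
how the network moves through meta-state space. Group differences in any of
these variables (or in the degree-distribution scaling exponent) are tested
with a linear mixed model with a random intercept per cell line, because
networks from one donor line are not independent.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `sampling_period_s` | 0.1506 | s | camera frame period at 6.64 Hz |
| `baseline_quantile` | 0.08 | – | 8th percentile of a trace: below almost all transient mass, above noise dips |
| `threshold_fraction` | 0.4 | – | event peaks must reach 40% of the trace maximum |
| `min_separation_frames` | 3 | frames | deterministic merge replacing manual event confirmation |
| `fc_cutoff` | 0.4 | – | absolute-correlation edge threshold; strict (> not ≥) |
| `window_width_frames` | 70 | frames | ~10.5 s, just above the slowest transient half-widths (all < 10 s), so one window spans a transient but not much more; 100 and 200 form the sensitivity set |
| `step_frames` | 1 | frames | maximal temporal resolution of wFC(t) |
| `n_components` | 4 | – | smallest basis that converges for most recordings while separating recurring patterns |
| `n_bins` | 11 | – | degree-histogram bins for the Poisson/Binomial fits |

The window count is a bookkeeping identity worth stating once:
`n_windows = n_frames − width + 1` for step 1, hence 1808 windows for 1877
frames at width 70. Only fully contained windows are used.

## The synthetic generator's stated world

`sim_config()` plants exactly the structure the downstream stages are
supposed to recover, nothing more:

* **Connectivity states.** K states (default 2) follow a first-order Markov
  chain with geometric dwell times (default mean 200 frames ≈ 30 s). The
  geometric law is the memoryless null — nothing in the pipeline estimates
  dwell-time shape, only means and counts, so the simplest law with a
  tunable mean is the right stated world.
* **Assemblies.** Each state partitions the neurons into co-active
  assemblies (default: two contiguous blocks whose cut rotates with the
  state index). Per frame, each assembly of the active state fires as a
  whole with probability `coactivation_prob` (default 0.05). A shared
  Bernoulli drive is the minimal mechanism that produces the
  block-correlation structure sliding-window correlation assumes.
* **Events and kinetics.** Baseline activity is Poisson per neuron (default
  0.02 Hz). Every event injects a difference-of-exponentials kernel
  (rise 0.3 s, decay 1.5 s → half-width ≈ 1.5 s, comfortably under the 10 s
  empirical bound; configurations implying ≥ 10 s are rejected unless
  `emulate_paper_kinetics = FALSE`). Additive Gaussian noise (sd 0.05
  relative to unit transient amplitude) and an optional multiplicative
  bleach trend (off by default — bleach correction is out of pipeline
  scope) complete the trace.
* **Structural graph.** A degree sequence drawn from P(k) ∝ k^−1.4 and
  realized as a simple graph. Support is truncated at the structural cutoff
  k_max = √(n⟨k⟩) (computed as a fixed point of the truncated law): beyond
  that bound heavy-tailed sequences are essentially never graphical, so a
  simple functional graph cannot contain such hubs in the first place.
  Realization uses stub matching with degree-preserving edge switches
  (igraph's `edge.switching.simple`), which preserves the drawn degrees
  exactly.
* **Seeding.** All randomness flows from one seed through named streams
  (`graph`, `states`, `spikes`, `noise`, `ica`), so identical configs are
  bit-identical and stages can be reproduced independently.

What the generator does **not** emulate: indicator biophysics (GCaMP/OGB
kinetics beyond a fixed kernel), photon shot noise, motion, spatial optics,
and any realistic inter-event statistics beyond the half-width bound — the
cultures' true event statistics are unknown, and defaults were chosen for
testability. A green recovery test therefore establishes that the pipeline
recovers *planted* block-switching structure at realistic geometry and
noise, not that it would resolve arbitrary biological dynamics.

## Numerical choices

* **Quantiles.** Baseline and quartile boundaries use linear interpolation
  between order statistics (R type 7), pinned by an independent
  sort-and-interpolate oracle in the tests.
* **Event definition.** "Half-width" is full width at half the event's peak
  amplitude, linearly interpolated between frames; amplitude is peak minus
  max(0, preceding valley). A peak exactly at the 40% threshold counts as
  detected (≥). The 40% threshold is applied to the global trace maximum
  (a robust maximum is a possible variant; the global rule is flagged in
  the docs).
* **Zero-variance handling.** Whole-recording zero-variance neurons are
  dropped (Pearson undefined) with their identities in a warning; a pair
  that is constant only *within a window* is imputed as correlation 0 so
  the wFC series stays rectangular for ICA, with an imputation count
  recorded.
* **Power-law estimator.** The scaling exponent is the slope of
  log₁₀(relative frequency) on log₁₀(degree). Two finite-sample corrections
  are on by default: each observed degree's frequency is normalized by the
  gap to the next observed degree (variable-width binning), and the
  regression is count-weighted. On exact contiguous power-law input both
  corrections are inert; on sampled sequences they remove the severe
  flattening caused by the singleton tail (many distinct high degrees each
  observed once put a horizontal shelf into the log-log plot; the plain
  estimator then recovers ≈ −0.6 for a planted −1.4 at n = 1000, the
  corrected one ≈ −1.36, as the tests measure). The uncorrected estimator
  remains available via `gap_normalize = FALSE, count_weight = FALSE`.
  Zero degrees are excluded (log undefined); Clauset-style ML tail fitting
  is deliberately out of scope.
* **Count-family fits.** Poisson/Binomial pmfs are evaluated at (possibly
  non-integer) bin centers through the Γ-function extension, and the SSE is
  minimized by a log-spaced grid scan plus golden-section refinement — the
  SSE surface flattens once the pmf's mass leaves the data range and can
  trap a bare golden-section search.
* **ICA.** Symmetric fixed-point FastICA with logcosh contrast on the
  SVD-whitened window × pair matrix; tolerance 1e-4, 200 iterations, up to
  5 restarts from derived sub-seeds. The sign of each component is fixed so
  its weight time series has nonnegative skewness; any fixed convention
  leaves all count/distance variables unchanged under global sign flip
  (asserted as a test). Networks that never converge are excluded from
  meta-state statistics and listed, not imputed — exclusions change the
  statistical sample and are therefore reported per run.
* **Weights and discretization.** Weights are the no-intercept OLS
  coefficients of each wFC row on the four patterns (each window is modeled
  as a linear combination of the patterns only). Quartiles are computed per
  component *within* each network — each network has its own basis, so
  weights are not comparable across networks. Positive and negative weights
  are discretized separately; negatives are ranked by ascending magnitude
  (the rule mirrors the positive side under sign flip; ranking by value was
  the other defensible reading). Boundary ties go to the lower quartile.
  Exact zeros get code +1 — a measure-zero event, messaged per occurrence.
* **Visits and hubs.** A "visit" is a maximal run of one meta-state, so a
  hub (≥ 2 visits) must be *returned to* after absence; with step-1 windows
  any state persists across many consecutive windows, which would make a
  window-count criterion vacuous. All runs of a hub state count as visits,
  including its first. Successive distances are evaluated between run
  representatives at transitions, not between all consecutive windows.
* **Time conversion.** Frame counts convert to seconds by multiplying by
  T = 0.1506 s (the frame period; a millisecond reading of that constant is
  inconsistent with the stated 6.64 Hz and is treated as a typo).
* **Mixed model.** `lme4::lmer`, REML for the reported fit; the deviance
  comparison between the covariate-free and covariate-adjusted models uses
  ML refits (REML deviances are not comparable across fixed-effect sets)
  with a χ²(2) likelihood-ratio decision at a configurable threshold
  (default 0.05). Significance of the diagnosis effect is the Wald Z with a
  standard-normal p — adequate at these sample sizes, as the calibration
  test measures; singular random-intercept fits are kept (variance 0, OLS
  fixed effects) with a warning. `n_possible_connections = n(n−1)/2` is
  exposed as an alternative covariate but never entered together with the
  quadratic term (they are collinear). Bonferroni over the nine variables
  is available but off by default.

## Persistence

Artifacts are delimited text (TSV) plus a JSON manifest with md5 checksums;
configs are JSON. HDF5 was considered and dropped: no HDF5 binding is a
guaranteed dependency here, and the tables this pipeline emits are small
enough that diffable text dominates.

## Known limitations

* The ICA basis, and hence the meta-state vocabulary, is per network;
  meta-states are not comparable across networks, only the nine summary
  variables are.
* The FCD matrix is O(n_windows²) and is therefore not computed by default
  in `run_pipeline()`.
* The Wald Z test relies on asymptotics in the number of cell lines;
  with very few lines a parametric bootstrap would be more defensible.
* The power-law fit is a regression summary of the degree histogram, chosen
  to match the field's common practice for these data; it is not a
  maximum-likelihood tail estimate.
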