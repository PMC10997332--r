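---
title: "Methods: synthetic visuomotor cohorts and the correlation analysis chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic visuomotor cohorts and the correlation analysis chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corticoflow)
```

`corticoflow` implements a complete analysis chain for widefield calcium
imaging of mouse dorsal cortex under different regimes of visuomotor
coupling, together with a synthetic-cohort generator that provides ground
truth for every stage. This vignette is the package's account of the model,
the parameter choices, and the numerical conventions.

## The recording model

A *session* is a 5-minute recording (100 Hz) of 12 regions of interest
(ROIs): V1, V2am, RSC, M1, A24b and M2 in each hemisphere, together with a
locomotion speed trace and a visual-flow speed trace. Sessions come in four
conditions:

* **closed loop** — visual flow is coupled to locomotion
  (`flow = coupling_gain * speed`), except during *visuomotor mismatches*,
  1-s halts of the flow injected at random times;
* **open loop** — a replay of visual flow that is decoupled from the
  mouse's current locomotion;
* **dark** — no visual flow;
* **grating** — drifting-grating blocks (6 ± 2 s duration, 4.5 ± 1.5 s
  gray intervals).

The generator builds each ROI trace as a weighted sum of interpretable
components, convolves it with a calcium-indicator kernel, and embeds it in
raw fluorescence:

```
x_i(t) = w_i L(t) + v_i F(t) + m_i M(t) + a_i Z_g(i)(t) + sum_k b_ik S_k(t)
dff_i  = scale * (x_i * kernel) + drift(t) + noise
raw_i  = F0 * (1 + dff_i)
```

with `L` the normalized locomotion drive, `F` the normalized flow drive,
`M` a mismatch drive (active only while locomoting, since the mismatch is a
withheld *consequence of movement*), `S_k` short-range latent factors,
`Z_g` a long-range latent shared between the anterior group (M1, A24b, M2)
and the posterior group (V1, V2am, RSC), and the kernel a single-exponential
decay (τ = 0.5 s, unit area). All latents are unit-variance AR(1) processes
(τ = 0.2 s).

### Latent structure and the treatment transform

Two design questions were genuinely open:

* **Short-range factors.** A single global factor cannot produce
  distance-*dependent* correlations — its contribution to any pair
  factorizes into per-ROI loadings. The generator therefore uses `n_latents`
  factors anchored at the ROI centers, with loadings
  `exp(-d(i, anchor_k) / loading_length_scale_mm)` (default scale 1.2 mm).
  Summed over anchors this yields a correlation that decays smoothly with
  pair distance, which is the feature the distance-resolved analysis needs.
* **The drug transform.** The treatment effect is modeled as a loss of
  long-range *coupling*: under `"drug"`, the correlation between the
  anterior and posterior streams of the long-range latent is set to
  `drug_longrange_scale` (`z_post = s z_ant + sqrt(1 - s^2) ε`). This keeps
  every ROI variance unchanged and scales anterior–posterior covariance
  *linearly* in `s`, so the median normalized long-range correlation change
  recovered by the analysis is `s - 1`. Scaling the loadings themselves
  would scale covariances by `s²` while also shrinking variances, which
  makes the injected factor unrecoverable from a ratio statistic; the
  coupling formulation is the generative model whose fingerprint the
  analysis is designed to read.

ROI coordinates default to a bregma-origin layout with a bregma–lambda
distance of 4.2 mm, arranged so that all 36 anterior–posterior pairs lie at
or beyond 0.9 bregma–lambda units (≈ 3.8 mm, the short/long-range cutoff)
and all 30 within-group pairs lie below it — i.e. the cutoff splits the 66
pairs into approximately equal halves.

### Locomotion

Locomotion is a two-state (quiescent/bout) semi-Markov process: exponential
quiescent gaps (rate `bout_rate_hz`, default 0.02 /s), gamma bout durations
(mean 5 s), and plateau speeds around 40 cm/s, comfortably above the
30 cm/s onset threshold. Bout *onsets are ballistic*: the speed rises to
plateau along a raised cosine at the acceleration limit (default
5000 cm/s², i.e. one or two samples at 100 Hz), while decelerations are
smooth (0.5 s). This choice is forced by the onset-validity rule itself: an
onset is valid only if neither behavior trace exceeded the quiescence level
(1 cm/s) anywhere in the 3 s before the 30 cm/s crossing, and any slow ramp
necessarily spends time in the 1–30 cm/s band immediately before crossing —
a generator with slow onset ramps would produce *no* valid onsets under the
rule as stated. The rule is kept exactly as the analysis defines it; the
generator's kinematics accommodate it.

The bout statistics themselves are free parameters of the generator (no
reference values exist for them); they were fixed once at values that give
a handful of well-separated supra-threshold onsets per 5-minute session.

### What the generator does and does not emulate

Emulated: bout-structured running; closed-loop coupling with 1-s mismatch
halts; open-loop replay (independent draw by default; set
`replay_from_session = TRUE` to replay the paired closed-loop session's
locomotion); grating blocks; distance-dependent latent correlations; a
calcium kernel; slow drift (default 0.01 ΔF/F per minute, emulating thermal
brightening); white noise; and injectable artifacts (seizure-like plateaus,
extra drift ramps, hemodynamic dips).

Not emulated: pixel-level vasculature and hemodynamic physiology,
indicator nonlinearity, eye movements, pharmacokinetics, session-to-session
nonstationarity. Tests that pass on these cohorts therefore validate the
*analysis chain* — its rules, statistics, and parameter recovery — not the
biological claims one could only test on real recordings.

## The analysis chain

* **ΔF/F** — `(F - F0)/F0` with `F0` the median of the recording; the
  output median is exactly zero and the transform is gain-invariant.
* **Drift correction** — subtraction of a running 8th-percentile baseline
  in a 62.5 s moving window (15 s is the conventional window for two-photon
  traces). The window is *centered* with edge truncation; a trailing window
  would phase-lag the baseline and leak drift into onset-locked averages.
  The percentile is the linear-interpolation quantile (type 7), and the
  compiled sliding implementation reproduces `stats::quantile` arithmetic
  bit-for-bit, so it equals a per-sample windowed quantile exactly.
* **Quality control** — a session is excluded iff the across-ROI mean ΔF/F
  stays above 0.30 continuously for strictly more than 10 s (an event of
  exactly 10 s is kept). The run length is counted in integer samples, so
  the decision is exact and independent of ROI order.
* **Onset detection** — upward crossings of 30 cm/s (first sample at or
  above threshold; at 10 ms bins sub-sample interpolation is pointless),
  vetoed by any activity above 1 cm/s in either behavior trace during the
  3 s pre-window (1 s for eGFP-style recordings). Candidates whose
  pre-window extends past the session start are invalid
  (`"incomplete pre-window"`). For visual-flow onsets the traces swap
  roles, which automatically restricts onsets to times without locomotion.
* **Alignment and baselines** — snippets from −5 s to +3 s at the native
  10 ms bin; events whose window leaves the session are dropped, never
  zero-padded. Baseline windows: (−200, 0) ms for unpredictable stimuli;
  (−2.9, −2.7) s for locomotion/flow onsets with a calcium indicator (the
  early window accommodates indicator offset dynamics and anticipatory
  activity); (−0.9, −0.7) s for eGFP. Subtraction zeroes the window mean
  exactly and is idempotent.
* **Triggered averages** — pooled means with per-bin 90%
  hierarchical-bootstrap bands (resample mice, then onsets within each
  selected mouse; 1000 replicates per band). One resampling is shared
  across the bins of a replicate by default so bands are trace-coherent;
  per-bin independent resampling is available by flag. With a single mouse
  the band degrades to an onset-level bootstrap with a warning.
* **Similarity** — per ROI, Pearson correlation between the closed- and
  open-loop average responses after a centered 1-s moving average (edges
  truncated), summarized as mean ± SEM over the 12 ROIs. The per-mouse V1
  variant averages left/right-hemisphere coefficients and excludes mice
  whose peak response is below 1% ΔF/F in either condition.
* **Pairwise correlations vs distance** — Pearson `r` per session for all
  66 pairs, distances normalized per mouse by the bregma–lambda length
  (planar distance; an approximation of axonal path length). Density maps
  bin (d_norm, r) on a fixed 40×40 grid (d ∈ [0, 1.6], r ∈ [−0.25, 1], so
  maps are comparable across cohorts; out-of-range values are clamped into
  edge bins), smooth with a Gaussian (σ = 1 bin) whose kernel is
  renormalized within the grid so total mass is conserved exactly, and draw
  the contour at 50% of the smoothed peak.
* **Treatment change** — per (mouse, pair), correlations are averaged over
  sessions within the before and after sets, then
  `(r_after - r_before)/r_before` is formed; pairs with `r_before = 0` are
  dropped (undefined normalization). Pairs split at 0.9 bregma–lambda
  units, with the boundary assigned to *long* range (≥ convention). When
  correlations across conditions are wanted, the package averages per-session
  coefficients rather than concatenating sessions (concatenation would let
  between-session offsets masquerade as correlation); this mirrors the
  per-session averaging used for the speed–activity analysis.
* **Inference** — hierarchical bootstrap of the mean (default 10,000
  replicates; mice, then sessions/onsets, each selected mouse contributing
  its own unit count), central quantile intervals, and one-sided p-values
  as tail proportions of replicate means versus zero, with replicates
  exactly at zero split evenly between tails. Family-wise correction is
  `α/m`. The rank-sum test enumerates the exact null distribution for
  group sizes up to 10 (midranks for ties) and otherwise uses the normal
  approximation with tie correction and 0.5 continuity correction. The
  one-way ANOVA reports the classical F with explicit conventions for
  degenerate designs (all-constant data: F = 0, p = 1; zero within-group
  variance with a between-group difference: F = ∞, p = 0), followed by
  per-group bootstrap p-values.

## Numerical conventions and problem sizes

ΔF/F is a dimensionless fraction everywhere inside the package; percentage
thresholds ("30%", "1%") are converted once at the configuration boundary.
Sample-count comparisons (QC durations, window arithmetic) use integers to
avoid floating-point boundary surprises. Session containers are plain-text
(CSV + JSON) with 17-significant-digit floats, so write→read round trips
are lossless.

The test suite runs the analyses at deliberately modest sizes chosen to
exercise the statistics at full fidelity: oracle equivalence on 50 random
traces (percentile filter) and 100 bout traces (onset detector); bootstrap
calibration on 1000 null cohorts of 10 mice × 5 sessions; decorrelation
recovery on cohorts of 4 mice × 2 dark sessions per treatment at coupling
scales 0.25/0.5/0.75; and treated-versus-saline discrimination over 100
repetitions of 2-mouse cohorts at the default scale 0.5. The
correlation-structure convergence check uses a 900 s noise-free,
drive-free session, where the sampling error of a correlation coefficient
(autocorrelation time ≈ 1 s after the calcium kernel) is small enough for
a 0.05 uniform band across all 66 pairs.

## Known limitations

* The generator's ROI geometry is one fixed layout; per-mouse geometric
  variation is supported through the `geometry` argument but not simulated
  by default.
* Hemodynamic artifacts are available only as injectable dips; no
  isosbestic correction is implemented (deliberately out of scope).
* The percentile-filter baseline biases the mean of detrended traces
  upward by roughly the distance between the signal's median and its 8th
  percentile; all correlation-based statistics are invariant to this
  offset.
* `pixel`-resolution analyses are limited to [response_map()] and movies
  supplied as arrays; there is no movie registration.
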