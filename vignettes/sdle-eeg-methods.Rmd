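---
title: "Detecting epileptiform discharges with the scale-dependent Lyapunov exponent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting epileptiform discharges with the scale-dependent Lyapunov exponent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdleeg)
```

## The problem and the model

Scalp EEG is noisy, and interictal epileptiform discharges — brief
paroxysmal transients such as spikes (20–70 ms, > 50 µV), sharp waves
(70–200 ms, 100–200 µV), spike/sharp-and-slow-wave complexes, polyspikes
and 10–25 Hz spike rhythms — must be told apart from ongoing background
activity. `sdleeg` does this with two complementary per-epoch features.

The first is spectral: the power spectral density integrated over
0.5–25 Hz, averaged over the 10 strongest of 19 channels. Synchronized
firing of large neural populations during a discharge raises this band
energy.

The second is dynamical: the scale-dependent Lyapunov exponent. Each
channel of a 4 s, 256 Hz epoch is delay-embedded with dimension $m = 2$
and delay $L = 1$ sample,
$$V_i = \big(x(i),\, x(i+L),\, \dots,\, x(i+(m-1)L)\big),$$
and all vector pairs whose initial separation falls inside a shell
$\epsilon_k \le \lVert V_i - V_j\rVert \le \epsilon_k + \Delta\epsilon_k$
are evolved in time. Their mean log-separation $\ln \epsilon_t$ defines an
error-growth curve, and the SDLE is its local slope,
$$\lambda(\epsilon_t) = \frac{\ln \epsilon_{t+\Delta t} - \ln \epsilon_t}
{\Delta t},$$
attached to the scale at which it was measured. For EEG the dominant
behaviour is the scaling law
$$\lambda(\epsilon) \sim -\gamma \ln \epsilon,$$
whose slope magnitude $\gamma$ measures how fast the signal loses
information as scale grows. Features are read off the scaling region:
$\lambda(\epsilon_1)$ at its smallest scale, $\lambda(\epsilon_3)$ at its
boundary, $\lambda(\epsilon_2)$ at the geometric midpoint, and their mean
$\bar\lambda$. Discharges are large, stereotyped, quasi-periodic events:
they raise the PSD feature and *lower* the small-scale divergence rate, so
the regularity ratio $\mathrm{PSD}/\lambda(\epsilon_1)$ separates the
classes with a single number.

Classification itself is deliberately off-the-shelf — a random forest
(100 trees) and an RBF-kernel SVM consume standardized feature pairs
$(\mathrm{PSD}, \lambda(\epsilon_1))$, $(\mathrm{PSD},
\lambda(\epsilon_2))$ or $(\mathrm{PSD}, \bar\lambda)$ — because the
separation is supposed to live in the features, not in classifier tuning.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `m`, `L` | 2, 1 | embedding dimension and delay (samples); adequate for 1024-point epochs at 256 Hz |
| `n_shells` | 4 | shells in the cascade |
| `first_fraction` | 0.1 | first-shell size as a fraction of the channel SD |
| `shrink` | 0.5 | shell-to-shell shrink factor |
| `theiler` | `(m-1)L + 1` | temporal exclusion for pair selection |
| `dt`, `t_max` | 1, 64 | evolution step and horizon (samples); 64 = ¼ epoch |
| `min_pairs` | 10 | shells with fewer pairs are dropped |
| `max_pairs` | 1000 (per-epoch driver) | deterministic per-shell pair cap |
| `r2_min` | 0.95 | scaling-region goodness-of-fit threshold |
| bandpass, notch | 0.1–70 Hz, 50 Hz | acquisition-chain reproduction |
| band, channels | 0.5–25 Hz, 10 strongest | PSD feature |
| `test_fraction` | 1/3 | stratified test share |

Shells are one-octave annuli $[\epsilon_k, 2\epsilon_k)$: with sizes
halving, consecutive shells tile a contiguous range of scales with no gaps.
Because shell sizes are proportional to the signal SD, the whole analysis
is amplitude-equivariant: rescaling a channel shifts its SDLE curve
horizontally by the log of the factor and leaves every $\lambda$ unchanged.

## Design choices made where the design was open

* **Embedding selection.** Delay and dimension are chosen by minimizing a
  divergence summary of time-dependent-exponent curves: the mean of
  $|\Lambda(t)|$ over an early-time window. The absolute value is
  deliberate: a collapsed embedding (e.g. delay = half period of a
  sinusoid, which folds the ellipse onto a line) produces near-zero evolved
  separations whose *signed* mean log-growth plunges to large negative
  values and would otherwise look "minimal". Penalising both divergence
  and collapse recovers the quarter-period delay for sinusoids and is
  stable on noise. The pair ensemble is held fixed over the evaluation
  horizon (pairs that would run off the series end are dropped up front),
  because a changing ensemble biases the curve. The summary shell is wide
  (0.1–1.1 SD) so that coarsely sampled periodic signals, whose pairwise
  distances live on a discrete grid, populate it at every candidate delay.
  The dimension is the smallest candidate whose summary is within 10% of
  the minimum over candidates.
* **"Strongest" channels** are those with the largest per-channel variance
  after filtering — variance is signal energy once the mean is removed —
  with ties broken by channel name for determinism; strength is judged per
  epoch.
* **Filtering** reproduces the acquisition chain (0.1–70 Hz bandwidth,
  50 Hz notch with Q ≈ 30) in the frequency domain: the epoch's DFT is
  multiplied by the squared magnitude response of a Butterworth design
  (band-pass order 4, band-stop order 2), which is exactly zero-phase.
  On fixed-length epochs this avoids the edge transients that forward–
  backward time-domain IIR filtering leaves: a full-epoch 50 Hz sinusoid
  is annihilated to numerical precision rather than to ~10%, and
  refiltering an EEG-like epoch changes per-channel RMS by under 1%.
* **Spectral estimation** is a single Hann-tapered periodogram, mean
  removed, renormalized so its trapezoidal integral equals the signal
  variance exactly (Parseval); band energies are trapezoidal integrals
  with interpolated band edges. A single segment is appropriate for
  1024-sample epochs; the absolute scale cancels between classes as long
  as it is consistent.
* **Combining curves.** The four shell curves (and then the ten channel
  curves) are averaged by interpolating onto the union of their scale
  grids and taking the arithmetic mean wherever at least one curve is
  defined; count-weighted averaging is a documented alternative the
  simplified mean deliberately avoids, for reproducibility.
* **Scaling-region search.** The longest contiguous window comprising at
  least 40% of the averaged curve (and ≥ 5 points) with $r^2 \ge 0.95$
  wins; among equally long windows the larger-scale one is taken. If no
  window qualifies the full-curve fit is returned flagged `degraded`.
  Window regressions use prefix sums, so the search is linear per window
  length.
* **Split sizes.** The stratified test share is
  $\lceil n_\text{class}/3 \rceil$, which reproduces the clinical
  bookkeeping of 66/34 training/testing normals and 360/180 epileptiform
  epochs out of 100 + 540.
* **Density overlap.** The regularity-ratio densities of the two classes
  (Gaussian kernels, Silverman bandwidth) locate a single crossing between
  the class medians — searched on extra-smoothed densities with a pooled
  doubled bandwidth, which damps kernel wiggles without shifting a
  crossing between comparable-spread modes — and the reported tails are
  the *empirical* sample masses on the wrong side of that crossing, which
  keeps them free of kernel-bandwidth bias. They lower-bound the error of
  any single-threshold rule on the ratio.
* **Error-doubling time.** $T_{db}$ is the first linear-interpolated
  crossing of $\ln\epsilon_0 + \ln 2$ on the largest-shell growth curve;
  by the telescoping of finite differences, integrating
  $\lambda(\epsilon_t)$ over $[0, T_{db}]$ returns $\ln 2$ up to
  interpolation error, which the tests check.

## Numerical details and degenerate inputs

Pair separations are evolved with surviving pairs only (evolved indices
must stay inside the series); a per-shell cap of 1000 pairs (deterministic,
evenly spaced) keeps large batches fast — a mean over 1000 log-distances
is statistically ample. Pairs with numerically zero evolved separation are
excluded from that time step's log-average. Constant channels are rejected
for shell construction (no scale); constant signals yield an all-zero PSD;
shells retaining fewer than `min_pairs` pairs are dropped with a message,
and an epoch in which no shell survives is an error. Coincident scale
abscissae are merged before curve averaging so every SDLE curve is a
function of $\ln\epsilon$.

## What the synthetic generator emulates — and what it does not

Normal epochs mix a shared $1/f$ source, channel-specific $1/f$ noise and
a 10 Hz alpha rhythm with common phase and channel-varying gain, at
25–35 µV RMS. Epileptiform epochs add discharge templates — biphasic
difference-of-Gaussian transients, half-sine slow waves of
1.2–1.8 × the transient amplitude, polyspike concatenations, > 1 s spike
trains — with the clinical duration/amplitude ranges, injected on 10–19
channels with gains 0.6–1 at random onsets. Transient subtypes occur as a
run of 6–12 events per epoch — the 1.5–3/s repetition typical of the
interictal runs captured in clinically marked 4 s epochs — and spike
amplitudes are drawn from 100–300 µV, the range of clearly annotated
scalp spikes (the clinical definition only bounds them below at 50 µV);
background amplitudes follow typical scalp EEG since no floor is given
clinically. These choices give every subtype the clear feature-level
contrast against background that the clinical scatter plots show. The default composition is 100
normal and 540 epileptiform epochs with the clinical subtype mix
(69/82/174/72/64/77/2).

The generator reproduces the *feature-level* structure the detector relies
on (higher PSD, lower small-scale SDLE for discharges) but not volume
conduction from dipole sources, eye-blink/EMG artifacts, electrode pops,
inter-subject variability, or discharge morphology beyond the parametric
templates. Passing the end-to-end benchmark on synthetic data therefore
demonstrates that the pipeline's machinery is correct and that the features
separate whenever the data carry this structure — it does not certify
clinical-grade accuracy on real recordings.

## Problem sizes used by the test-suite and acceptance runs

The oracle-equivalence checks run on ≤ 300-point series where an $O(N^2)$
brute-force reimplementation is exact to 10⁻⁹. Class-contrast properties
use 50 epochs per class; the end-to-end benchmark uses the full 640-epoch
composition with the per-shell pair cap of 1000. Scaling-law recovery uses
30-point curves with 1% noise over 20 seeds.

## Known limitations

* $m = 2$, $L = 1$ are good working values for 256 Hz scalp EEG but are
  not re-optimized per epoch by default (`select_delay()` /
  `select_dimension()` are available).
* The three-parameter variant that adds the attractor size
  $\epsilon_\infty$ is exposed (`eps_inf` in the feature table) but not
  tuned or used by the default algorithms.
* Discrimination among the seven discharge subtypes is out of scope; the
  label is binary.
* EDF support covers plain EDF writing and EDF/EDF+ reading with a single
  sampling rate across EEG channels; annotation channels are skipped, not
  parsed.
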