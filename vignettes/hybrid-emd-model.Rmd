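---
title: "A hybrid elementary motion detector: model, analyses, and synthetic recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid elementary motion detector: model, analyses, and synthetic recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flyemd)
```

## The model

Direction selectivity in the fly's first motion-sensing neurons (the T4
cells of the ON pathway) can arise from two classical mechanisms:
*preferred-direction (PD) enhancement*, where a delayed flanking signal
multiplies the direct signal (the Hassenstein–Reichardt idea), and
*null-direction (ND) suppression*, where a delayed flanking signal divides
it (the Barlow–Levick idea). `flyemd` implements a three-arm unit that
combines both in a single detector:

$$R(t) \;=\; \frac{\bigl(k_E\,\mathrm{LP}(E) + c\bigr)\,\bigl(k_D\,D + c\bigr)}
                 {k_S\,\mathrm{LP}(S) + c}$$

where $E$, $D$ and $S$ are the front-end (L1) signals of three adjacent
visual columns — the enhancing arm one column to the null side (relative
position $-1$), the direct arm at the home column ($0$), the suppressing
arm one column to the preferred side ($+1$) — $\mathrm{LP}$ is a
first-order low-pass with $\tau = 250$ ms, and $c$ is a DC term that keeps
the denominator positive and carries the flicker response. Motion from
$-1$ toward $+1$ is the preferred direction ("upward" for the layer-3 T4
analog).

The front-end models lamina cell L1: the local luminance is high-pass
filtered (first order, $\tau = 250$ ms), 10% of the DC value is added
back, and the result is half-wave rectified. Arrays sum one unit per
column (units missing an input column at the raster edge are dropped), and
the opponent "tangential" stage subtracts the mirrored array, as lobula
plate tangential cells subtract oppositely tuned T4 inputs.

### Parameters

| parameter | default | units | role |
|---|---|---|---|
| `k_e`, `k_d`, `k_s` | 5, 5, 10 | – | arm weights; ablations zero `k_e` or `k_s` |
| `dc_term` | 1.0 | – | additive constant per arm; sets the resting response to 1 |
| `tau_lp_s` | 0.25 | s | delay filter of the E and S arms |
| `dc_fraction` | 0.1 | – | fraction of DC restored by L1 |
| `tau_s` (L1) | 0.25 | s | L1 high-pass constant |
| raster | 40 columns, 5° | – | 200° extent, matching the stimulus array |
| movie grid | 1°, 10 ms | – | default stimulus resolution |

Two conventions in the response expression are genuinely open and were
fixed as follows:

* **DC placement.** The DC term is added *after* weighting
  ($k\,x + c$), so the resting response is $c^2/c = c = 1$ regardless of
  the weights, and ablated variants keep the same resting point. The
  alternative, $k(x + c)$, would make the rest level depend on which arm
  is ablated and complicate every cross-variant comparison.
* **"DC value" of the front-end.** By default the DC is the temporal
  mean of the luminance trace (`dc_mode = "mean"`), so a trace that
  contains a pulse has a slightly elevated resting floor. A fixed
  background level (`dc_mode = "background"`) is available; under it a
  lone pulse on the suppressing side produces *exactly* no positive
  deflection, whereas under the mean convention a small rebound (about 1%
  of the direct-arm response, far below any detection threshold) remains.

## Stimuli

Stimuli are space–time luminance movies in $[0,1]$ at 1° and 10 ms
resolution, point-sampled at the 40 column centers (a boxcar average over
one 5° pitch is available; for the stimuli used here both rules coincide,
since pulses fill a column's footprint uniformly). Pulse protocols place
450 ms (model) or 472 ms (single-column protocol) rectangles of amplitude
1.0 on individual columns; apparent-motion sequences use 472 ms
onset-to-onset timing by default, with the 400 ms LED-arena timing
available through the same arguments.

Gratings are parameterized around mean luminance 0.5 so that contrast 1.0
spans the full range. Direction is handled by projecting the grating onto
the 1-D column axis: the spatial frequency scales with $\cos\theta$
(computed with `cospi` so $\theta = 90°$ is exactly full-field flicker and
the tuning is exactly even in $\theta$). Grating runs choose the time step
as an integer divisor of the grating period near 10 ms with at least 24
samples per cycle, so the measurement window always holds a whole number
of cycles; frequencies above ~10 Hz are thereby sampled finely enough to
avoid aliasing.

## Numerical choices

* **Filters** use the exact exponential discretization
  $y_n = a\,y_{n-1} + (1-a)x_n$, $a = e^{-\Delta t/\tau}$, which is the
  exact solution for a piecewise-constant input and therefore robust to
  the choice of $\Delta t$; the high-pass is the exact complement
  $x - \mathrm{LP}(x)$. Filters initialize at steady state (input held at
  its first sample for all past time), so constant inputs are exact fixed
  points and a settled baseline needs no burn-in.
* **Baselines.** Runners prepend 1.5 s (≥ 5τ) of background before
  stimulus onset; with steady-state initialization the recorded baseline
  equals the rest response exactly.
* **Tuning amplitudes.** Grating responses are quantified as the mean
  baseline-subtracted response over whole cycles after a 1 s transient
  (peak is available). For *cross-variant* selectivity comparisons the
  raw mean response level (no baseline subtraction) is used instead: the
  ablated variants' periodic responses ride mostly below their resting
  level, so their baseline-subtracted amplitudes clip to zero and a
  direction-selectivity index on them would be undefined, while the
  response level is positive by construction. Under the level convention
  the full model is the most direction-selective
  (DSI ≈ 0.16 vs ≈ 0.09 and ≈ 0.06 for the ablations at 1 Hz), and the
  ablated variants show null-direction responses almost as large as their
  preferred-direction responses, as expected for half-detectors.
* **Receptive-field maps** align each cell by its maximum (ties broken by
  the first maximum in row-major raster order — deterministic), normalize
  by it, then average; dispersion is SEM = sd/√n. For noisy synthetic
  recordings, per-column amplitudes use the *mean* over the stimulus
  epoch: the peak of a noisy average has an upward extreme-value bias of
  order $\sigma\sqrt{2\ln m}$ (m samples in the epoch) that no amount of
  cell averaging removes, while the epoch mean is unbiased. The peak
  measure remains the default for clean, well-averaged traces.
* **Nonlinear-component null test.** For a linear cell the nonlinear
  component (sequence response minus time-shifted flicker sum) is zero to
  machine precision without noise. With trial noise, each sample of the
  component has standard deviation $\sigma\sqrt{(1+K)/n_{\text{reps}}}$
  ($K$ flicker conditions); the test statistic is the mean over the
  stimulus epoch compared against three times its standard error — a
  proper 3σ z-test, in contrast to a bound on the pointwise extremum of
  thousands of samples, which would be exceeded by chance with
  probability near one.
* **Spatial segregation threshold.** "Enhancement only between −1 and 0,
  suppression only between 0 and +1" is operationalized as: the off-side
  nonlinear components are below 20% of their on-side counterparts (the
  model gives ≈ 8%).
* **Delay grid.** Onset-delay tuning scans 0–1.5 s in 59 ms steps (one
  eighth of the 472 ms pulse), simulated at 1 ms so every delay lands on
  the grid.

## The synthetic-data generator

`simulate_recording()` emulates the statistical structure of single-column
calcium-imaging data so every analysis stage can be exercised without
recordings: a hexagonal raster of 19 columns (two rings) in axial
coordinates with the three anatomical axes (D–V, DL–VF, DF–VL); per-column
receptive-field amplitudes — ring presets (1, 0.5, 0.25) for the wide
T4-like field and (1, 0.3, 0.12) for the narrow L2-like field, or an
isotropic Gaussian over lattice distance; a peak-normalized
single-exponential indicator kernel (τ = 0.3 s, applied with unit DC gain
so long pulses saturate at the rf amplitude); additive i.i.d. Gaussian
noise per sample; and 3 repetitions per condition. Noise streams are keyed
by (condition, repetition) and the base seed, so recordings are
bit-identical under the seed and stable when conditions are added; the
JSON manifest written by `write_recording()` suffices to regenerate a
recording exactly.

The generator's "emd" cell routes stimuli through the detector unit
centered on the raster, with optical cross-talk between columns given by
the rf ring profile — a phenomenological stand-in for the eye's Gaussian
acceptance angle. What the generator does **not** emulate: photoreceptor
adaptation, OFF-pathway dynamics, bleaching, motion artifacts, or scanning
statistics of two-photon imaging. Passing tests on this generator
therefore show that the *analysis procedures* are correct and that the
*model* has the claimed properties — not that real recordings would be
free of those confounds.

## Problem sizes

The shipped tests and the acceptance script run the model at the sizes the
analyses need, chosen once: 10 random 10 s traces at 1 ms for the filter
oracle; a 9-point log-spaced 0.1–10 Hz frequency grid; 12 directions at
1 Hz; 26 onset delays; 20 random protocols for the linearity null; 10
synthetic cells × 19 columns × 3 repetitions for receptive-field
recovery. A full run of everything takes well under a minute.

## Known limitations

* The detector is algorithmic, not biophysical: no conductances, no
  dendritic geometry, no synaptic identities — the medulla cell types
  feeding the three arms are deliberately left unassigned.
* Only the ON half (T4 analog) is modeled; there is no T5/OFF pathway.
* The 1-D column axis with a $\cos\theta$ projection reproduces the even,
  front-back-symmetric part of direction tuning only; a 2-D hexagonal
  detector lattice would be required for anything finer.
* The experimental numbers reported in single-column studies (surround
  percentages, ≈ 500 ms optimal delay, ≈ 90° tuning half-width) are
  measurements on live neurons; the package reproduces their qualitative
  structure (interior delay optimum, sharp even tuning, suppressed
  dorsal pairs) rather than those numerals.
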