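---
title: "Quantifying beat-to-beat calcium current alternans: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying beat-to-beat calcium current alternans: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icalternans)
```

## The problem

Cardiac alternans — a beat-to-beat alternation in the electrical response of a
myocyte — is a recognised precursor of atrial fibrillation. In voltage-clamped
cardiomyocytes it shows up as alternation of the L-type calcium current
(I~Ca~) and of the Na^+^/Ca^2+^-exchanger tail current (I~Tail~) across
consecutive stimulation sweeps. `icalternans` implements an end-to-end
pipeline for detecting and quantifying this alternation in whole-cell
voltage-clamp sweep trains: preprocessing, per-sweep feature extraction, a
normalized alternation index, group statistics, and a circuit-level simulator
that provides analytically known ground truth for validation.

## Stimulation protocol and the six features

Each sweep applies a hold at −80 mV, a 50 ms pre-pulse to −45 mV (inactivating
I~Na~), a 200 ms depolarization to 0 mV (eliciting I~Ca~ after the outward
capacitive transient), and a return to −80 mV (eliciting the inward tail
current). The protocol is repeated 30 times per cell at 0.5–2 Hz. Six features
are extracted per sweep — the I~Ca~ peak amplitude, the charges Q~Ca~ and
Q~Tail~ (trapezoidal areas relative to an m-point steady-state baseline,
starting 2 ms after the respective voltage transition), the single-exponential
inactivation constant τ of I~Ca~, and the fast/slow tail constants τ~1~ < τ~2~
from a double-exponential fit — giving the canonical 30 × 6 feature matrix per
cell. Two auxiliary peaks (capacitive and tail) support the region-of-interest
logic.

## Preprocessing

The current is smoothed with a **causal rectangular moving average**. The
window length is not fixed a priori: `window_length_from_energy()` picks the
smallest `L` that removes at least a fraction `k` (default 0.02) of the trace
energy; on noise-dominated traces this gives `L = 2`, and on this package's
synthetic sweeps (where the deterministic currents carry most of the energy)
typically `L = 3`. We chose the *causal* truncated-window edge rule so that the
sharp capacitive transients cannot leak backwards in time; the price is a
group delay of `(L−1)/2` samples, which the extractor compensates when it
anchors integration windows on the (undelayed) command voltage. The recorded
command voltage is snapped onto the theoretical levels {0, −45, −80} mV by
nearest-neighbour interpolation, with exact ties resolved toward the more
negative level for determinism.

## Capacitive-transient removal

Q~Ca~ must exclude the area under the capacitive transient. Because the
pre-pulse step is purely passive (sodium current eliminated chemically,
calcium channels still closed at −45 mV), its transient is a clean template of
the linear circuit's step response. `prepare_sweep()` fits
`a·exp(−t/τ) + c` to the pre-pulse transient — skipping the first 0.5 ms after
the extremum, where the acquisition filter still shapes the edge, and
extrapolating the amplitude back to the extremum — and subtracts the
voltage-scaled transient (not the offset; steady leaks belong to the
baselines) from the depolarization and repolarization segments. This is the
P/N-style leak-subtraction idea long standard in electrophysiology. The 2 ms
offsets and the transient-re-crossing guard for the Q~Ca~ window start are
retained on top of it.

## Peak detection

`detect_peaks()` finds samples strictly larger than both neighbours and
filters them by minimum height (100 pA), minimum topographic prominence
(10 pA), minimum interpolated half-prominence width (1.163 samples) and
minimum separation (63 samples; of two closer candidates the larger
survives). Local minima are found by running the identical procedure on the
sign-flipped trace. Reported protocol-peak *amplitudes* are measured relative
to the region's steady-state baseline and read as the mean of a short centered
window (default 9 samples) around the detected extremum — the "peak mean of n
points" read-out familiar from ephys analysis software, which keeps the
single-sample noise out of the amplitude. A noiseless tail decays
monotonically from its window edge and therefore has no interior local
minimum; in that case the window extremum is used, guarded by the same height
threshold so that absent currents are still reported as missing rather than
fabricated.

## Exponential fits and model selection

The I~Ca~ decay from the calcium peak to the step end is fitted with
`a·exp(−(t−t0)/τ) + c`; the tail decay with
`a1·exp(−t/τ1) + a2·exp(−t/τ2) + c`, time constants returned sorted. Fits use
Levenberg–Marquardt (`minpack.lm`) with data-driven initialization (offset
from the trailing samples, amplitude from the first sample, τ from the 1/e
crossing; the double fit is seeded from the single fit at τ/3 and 3τ with a
70/30 amplitude split), relative tolerance 1e−10 and at most 400 iterations.
Failures and non-positive time constants yield a non-converged result, never
an exception. Model choice for the tail uses the least-squares AIC
`n·ln(RSS/n) + 2k` with the conventional parameter counts k = 4 (single) and
k = 5 (double); only the AIC *difference* matters for selection, ties favour
the simpler model, and a numerically perfect fit is scored with a large
negative sentinel instead of −∞. Nearly equal fitted constants or a vanishing
component amplitude mark a double fit as degenerate (non-identifiable). In the
single-exponential model the onset time t0 is fixed at the fitted segment's
origin rather than estimated — a free t0 is algebraically redundant with the
amplitude.

## The alternation index

For any per-sweep feature series `m(t)`, the successive differences
`D(t) = m(t) − m(t−1)` and

$$\mathrm{CIdx} = \frac{\operatorname{mean}(D^2)}{\max(D^2)} \in [0, 1]$$

quantify alternation: a perfect square-wave alternation has all squared
differences equal and scores exactly 1; an isolated jump in an otherwise flat
series scores ≈ 1/(N−1). The index is invariant to shifting and rescaling the
series and deliberately *not* invariant to permuting it. A perfectly constant
series (max D² = 0) carries no alternation evidence; we define CIdx = 0 with a
degeneracy flag rather than letting 0/0 propagate. Missing sweeps drop
pairwise: only differences between adjacent available sweeps enter, and the
effective N is the usable difference count plus one.

## The simulator and its calibration

The synthetic signal chain is: protocol waveform → passive one-compartment
circuit + parametric ionic currents → 4th-order Bessel low-pass → additive
Gaussian noise. Because the command is piecewise constant, the passive
response (membrane R~m~ ∥ C~m~ behind access resistance R~a~, seal shunt R~s~,
resting EMF −90 mV) is computed by exact per-segment exponential updates, with
τ~cap~ = C~m~·(R~a~∥R~m~) ≈ 0.80 ms at the defaults (C~m~ = 55 pF, R~m~ =
500 MΩ, R~a~ = 15 MΩ, R~s~ = 1 GΩ). The amplifier (500 MΩ feedback, "medium"
gain) is treated as an ideal transimpedance stage; its behaviourally relevant
element at analysis scale is the output filter, modeled as the analytic Bessel
prototype (reverse Bessel polynomial poles, −3 dB normalization) discretized
by the bilinear transform with prewarped cutoff. The cutoff is configurable
and defaults to 2.9 kHz, a standard whole-cell acquisition bandwidth; the
sampling frequency defaults to 10 kHz (hardware maximum 200 kHz).

Ionic currents use waveform families chosen so every feature is analytically
known: I~Ca~ is `−peak·(1−e^{−t/τ_act})·e^{−t/τ}` (normalized so the extremum
equals the nominal peak) and the tail is an inward double exponential.
Defaults describe a large, healthy human atrial myocyte: peak I~Ca~ 1800 pA
(~33 pA/pF at 55 pF — the upper range of healthy atrial I~CaL~ density, chosen
so the synthetic pulse has the visibility of representative experimental
traces), τ~act~ = 0.8 ms, τ = 25 ms, tail 600 pA with τ~1~ = 4 ms, τ~2~ =
40 ms and 65 % of the amplitude on the fast component.

**Noise calibration.** The experimental noise level was estimated with the
robust MAD estimator as σ~noise~ = 188, *reported as a mean noise variance*.
We treat it as a variance (pA²), i.e. an RMS noise of √188 ≈ 13.7 pA — a
typical whole-cell noise floor at ~3 kHz bandwidth — rather than as an RMS of
188 pA, which would exceed realistic recording noise by more than an order of
magnitude and would drown every sub-percent validation target. The noise
model's default parameter therefore remains 188, documented as noise power,
and `mad_noise_sigma()` (MAD of first differences scaled by 1/√2, which
suppresses slow signal content) recovers √188 on simulated traces. The
recorded command voltage additionally gets 0.5 mV RMS readout noise, which the
snapping step removes exactly.

**Alternation model.** With depth d, even-numbered sweeps scale the calcium
amplitude by (1+d) and the tail by (1−d); odd sweeps the reverse — calcium and
tail charges alternate out of phase, mirroring the negative feedback of
sarcoplasmic-reticulum calcium release on I~Ca~. Datasets default to 13
uniform (d = 0) plus 11 alternant (d = 0.3) cells with ±20 % uniform per-cell
jitter on the ionic parameters.

**Ground truth.** The per-sweep ground truth is the set of feature values of
the noiseless, Bessel-filtered ionic component, evaluated with the *same*
regions of interest, m-point baselines and windowed peak read-out the
extractor uses; time constants are the generating parameters (a linear
time-invariant acquisition chain does not alter decay rates). The closed-form
total tail charge `peak_tail·(a1·τ1 + a2·τ2)` is exposed separately as
`analytic_tail_charge()` and is the Fs → ∞ limit of the trapezoidal charge.

## What the validation does and does not show

Feature recovery on noiseless simulator output is exact to ≲0.1 % for peaks
and areas and ≲0.5 % for time constants (the residual τ error reflects the
still-rising activation gate under the early decay window). Under calibrated
noise, the median relative errors over 20 noise seeds are ≈0.6–1.0 % for
Q~Ca~, ≈0.3 % for the peak amplitude and ≈0.5 % for τ. The Q~Ca~ figure is at
its theoretical floor: the 20-point steady-state baseline carries
13.7/√22 ≈ 2.9 pA of noise, and across the ~198 ms integration window that
alone contributes a ~1.2 % error SD — the procedure's own definition, not an
implementation artifact. A discrimination experiment (13 uniform vs 11
alternant cells, CIdx of Q~Ca~ per cell, two-sided Wilcoxon rank-sum)
separates the regimes at p ≤ 0.01 across seeds.

The generator emulates protocol structure, circuit transients, acquisition
filtering and stationary Gaussian noise with per-cell parameter jitter. It
does **not** emulate run-down, seal drift, series-resistance changes,
non-stationary or 1/f noise, stochastic channel gating, or physiological
alternans dynamics (the phase rule is imposed, not emergent) — so passing
validation demonstrates correctness of the *measurement pipeline*, not
biological fidelity of any particular recording.

## Group statistics

Two-sided Wilcoxon rank-sum tests compare uniform and alternant populations;
for combined n ≤ 20 the p-value is computed by exhaustive enumeration of the
mid-rank assignments (exact even under ties), beyond that by the normal
approximation with tie-corrected variance and continuity correction. Group
summaries report mean ± SEM and the star notation ns/*/**/***/**** at the
inclusive thresholds 0.05, 0.01, 0.001 and 0.0001. Sweep-level pooling and
per-cell summaries are both possible; the shipped comparison tables operate on
per-cell alternation indices.

## Numerical choices and problem sizes

Tie-breaks, tolerances and degenerate paths are fixed for determinism and
documented on the functions: voltage ties snap negative; AIC ties select the
single model; a constant feature series scores CIdx 0 (flagged); all-zero
traces are rejected by the energy heuristic rather than dividing by zero.
The shipped test suite exercises the full chain at the canonical 10 kHz/1 Hz
protocol for the validation studies and at 2 Hz (half-length sweeps) for
structural tests; Monte-Carlo checks use 20–100 seeded replicates and the
null-calibration of the group test 2000 replicates — sizes chosen to make the
statistical assertions stable at desk scale.

## Known limitations

The pre-pulse-template subtraction assumes circuit linearity across the
protocol's voltage range; strongly voltage-dependent stray capacitance would
violate the scaling. The Q~Tail~ window runs to the sweep end, so its
baseline noise contribution grows with the inter-stimulus interval at low
stimulation frequencies. The single-exponential τ of I~Ca~ is a deliberate
simplification of a two-gate decay; its small positive bias on rise-×-decay
waveforms is inherent to that model choice. File input is limited to the
package's open ASCII dialect — proprietary amplifier bundles must be exported
to text first.
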