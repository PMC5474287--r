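---
title: "Reconstructing ground reaction force from an instrumented treadmill: methods"
author: "grfcomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing ground reaction force from an instrumented treadmill: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grfcomp)
```

## The measurement problem

A force treadmill built by mounting an ordinary treadmill on load cells is an
*indirect* measurement instrument: the transducers sit under the frame, so
they report the force transmitted *through* the treadmill structure, not the
ground reaction force (GRF) applied at the track surface. If the structure
behaved as a distortionless transmission — output a scaled, delayed copy of
the input, i.e. constant amplitude response and phase linear in frequency —
the two would be interchangeable. A real frame is a resonant mechanical
system: its transmission is flat only well below the first structural mode
and oscillatory above it.

Treating the frame as a single second-order mode with natural frequency
$f_n$ and damping ratio $\xi$, the amplitude and phase responses in the
dimensionless frequency $u = f/f_n$ are

$$|H(u)| = \frac{1}{\sqrt{(1-u^2)^2 + 4\xi^2 u^2}}, \qquad
\angle H(u) = -\arctan\frac{2\xi u}{1-u^2},$$

with the low-frequency limits $|H| \to 1$ and $\angle H \to -2\xi u$. Since
roughly 99% of walking vertical-GRF power lies below about 12.75 Hz, a mount
at $f_n = 45$ Hz already misreads that band edge by 8.7%
($|H(12.75/45)| \approx 1.087$); pushing $f_n$ to 160 or 219 Hz shrinks the
error to 0.6% and 0.3% — the hardware route, which demands a light, stiff and
expensive frame ($f_n = \sqrt{k/m}/2\pi$).

`grfcomp` implements the software route: measure the transmission transfer
function $H(f) = Y(f)/X(f)$ once, with hammer strikes against a reference
force platform on the track, then reconstruct the GRF from any later
measurement by inverse filtering,
$x_c(t) = \mathcal{F}^{-1}\!\left[\hat{H}^{-1}(f)\, Y(f)\right]$.

## Identification

`estimate_transfer_raw()` is the textbook single-strike ratio
$\hat H = Y/X$. The default, `estimate_transfer_h1()`, is standard
modal-testing practice: the H1 estimator
$\hat H = S_{xy}/S_{xx}$ from cross- and auto-spectra averaged across
repeated strikes, with the coherence
$\gamma^2 = |S_{xy}|^2/(S_{xx} S_{yy})$ reported per bin. With one noiseless
trial both coincide exactly.

Three practical details, each a deliberate design choice:

* **Excitation masking.** Hammer spectra roll off, and dividing by near-zero
  bins amplifies noise without bound. Bins where $\sqrt{S_{xx}}$ falls below
  `eps_id` (default $10^{-3}$) of its peak are flagged `masked`, never
  divided, and the masked fraction is reported. Nothing is extrapolated into
  unexcited bands.
* **Baseline correction.** Each trial's pre-trigger mean is subtracted per
  channel: the load cells carry the full static preload of the frame, and
  the ratio concerns the dynamic component only.
* **Windowing.** Rectangular by default — a contained transient needs no
  taper; an exponential window is available for noisy decaying tails.

## Inversion

The raw inverse $1/\hat H$ explodes wherever the structure antiresonates, so
`invert_transfer()` uses the Tikhonov (water-level) form

$$\hat H^{-1}_\lambda = \frac{\overline{\hat H}}{|\hat H|^2 + \lambda^2},
\qquad \lambda = \texttt{reg\_eps} \cdot \max|\hat H|,$$

whose magnitude is bounded by $1/2\lambda$. Defaults: `reg_eps = 1e-2`;
inversion band limited to `f_max = 150` Hz (the acquisition filter cutoff —
above it the record carries no credible content), with bins outside the band
zeroed. The static (DC) component is handled separately: the measurement
mean is removed before inversion and added back unchanged (`dc_gain =
"unity"`), because impact trials are baseline-corrected and so say nothing
reliable about the DC gain, while body weight must survive compensation. A
model whose true static gain differs from 1 can use `dc_gain =
"identified"`.

### Transform conventions

All spectral operators share one convention: unscaled forward DFT, inverse
divided by `nfft`, one-sided storage with the DC and Nyquist bins forced
real. The default transform length is the signal length itself (rounded up
to even), i.e. a *circular* application with no padding. This was a
considered deviation from the common pad-to-2x habit: padding plus
truncation discards the post-record ringing tail, so the forward and inverse
operators stop being exact inverses of each other, and a round trip through
a simulated transmission leaves edge artifacts on the order of $10^{-4}$ to
$10^{-2}$ in energy ratio. The circular pair is exactly invertible; it is
also the physically right treatment for steady periodic gait (circularity =
steady state) and for transients fully contained in the record (where
circular and linear convolution coincide). An explicit `nfft` argument
provides zero-padding when records end abruptly mid-motion.

## The acquisition filter

The modeled measurement chain low-pass filters at 150 Hz with a 20th-order
Butterworth applied with exactly zero phase — offline processing permits
non-causal filtering, and zero phase is the $t_d = 0$ case of distortionless
transmission. `lowpass_zero_phase()` realizes the design as cascaded
second-order sections (a direct-form order-20 polynomial is numerically
unusable) applied forward and backward with odd-reflection edge padding, so
the effective magnitude is the squared single-pass response (−6 dB at the
cutoff). Forward-backward filtering of a record that ends mid-oscillation
leaves edge transients regardless of implementation; stopband attenuation
claims are therefore evaluated on the record interior.

## The THD fidelity metric

Reconstruction accuracy is scored as

$$\mathrm{THD} = \frac{\int_0^T (\hat x(t) - x(t))^2\,dt}
{\int_0^T x^2(t)\,dt},$$

the energy of the estimation-error waveform relative to the energy of the
true signal — a whole-waveform metric, not the audio-engineering
harmonic-by-harmonic THD. Two conventions circulate (with and without a
square root); the package reports the energy ratio as canonical, matching
the metric's verbal definition, and carries `thd_sqrt` alongside. Signals
are compared at identical indices with no lag search: the compensation path
is zero-phase, so any residual delay is genuine error and should be scored.

The companion statistic `bandwidth_98()` is the smallest frequency below
which 98% of the one-sided spectral energy lies. The DC bin is included by
default — the body-weight baseline carries real energy in a
walk-on-the-spot record — and excludable via `include_dc = FALSE`.
`bandwidth_thd_association()` gives the Pearson correlation (with two-sided
t-test p-value) between per-record THD and bandwidth: wider-band GRF pushes
more energy into frequencies where identification is noisier, so a positive
association is expected.

## The synthetic-data generator

No public recordings of paired track-surface/load-cell force exist, so the
simulator is the package's ground-truth oracle, emulating both experimental
phases.

**Walk-on-the-spot GRF** (`synth_walk_grf()`): body-weight baseline (default
717 N, a 73 kg adult) plus one stance profile per step at 2 steps/s for
20 s — two raised-cosine lobes (weight acceptance and push-off, half-width
0.11 cycle) and a 10 ms-half-width initial-contact spike. The spike matters:
it is what extends the spectrum into the 30–80 Hz range where treadmill
modes live, as heel-strike transients do in real gait. Under the defaults
the record has a 98% bandwidth of ~10 Hz, 99% of its power below ~13 Hz
(matching the walking literature), and peaks near 1.7 body weights. The
fluctuation is zero-mean by construction, so the time mean equals body
weight exactly; with zero noise and zero asymmetry the signal is exactly
periodic. What the generator does *not* emulate: stride-to-stride timing
variability, double-support overlap between feet, center-of-pressure travel
and shear coupling. Passing tests on this family therefore demonstrate the
algorithm under a realistic amplitude/bandwidth regime, not performance on
any individual human record.

**Hammer strikes** (`synth_hammer_impact()`): half-sine pulses, default 5 ms
base width so that the first spectral null ($1.5/\mathrm{width}$ = 300 Hz)
stays above the 150 Hz analysis band — a 10 ms pulse would put a null
exactly at 150 Hz. The sampled pulse is rescaled so its discrete integral
equals the analytic impulse $\text{peak} \cdot w \cdot 2/\pi$ exactly; at
1024 Hz naive sampling misses the area by $\sim 10^{-3}$ relative, and the
impulse is what sets excitation level.

**Transmission** (`treadmill_model()`): a weighted sum of damped
second-order modes, weights normalized so $H(0)$ equals the static gain
exactly (body weight transmits undistorted at DC). The default three-mode
frame (28/65/110 Hz, $\xi$ 0.04–0.06) reproduces the qualitative picture of
a measured frame response — flat below ~5 Hz, oscillatory above — and
distorts the default walk record by ~3.6% THD; it is a plausible stand-in,
clearly synthetic, not a reconstruction of any measured instrument.

## Numerical choices and degenerate inputs

* Undamped resonance exactly on an evaluation point ($u = 1$, $\xi = 0$) is
  an error, not an `Inf`.
* The phase response uses the continuous $0 \to -\pi$ branch through
  resonance (`atan2`), matching physical second-order lag; the
  principal-value arctangent would flip sign above $u = 1$.
* A spectrum whose DC or Nyquist bin has a significant imaginary part
  (relative $10^{-9}$) is rejected as non-conjugate-symmetric rather than
  silently realified.
* Transfer functions estimated on one grid are linearly interpolated (real
  and imaginary parts separately) onto the measurement's grid; a target bin
  is masked whenever a bracketing source bin was masked.
* CSV rejection messages name the offending row/column; a time grid is
  uniform only to $10^{-6}$ relative.

## Problem sizes used in the shipped checks

The test suite and worked examples run entirely on generated data at the
acquisition geometry the package models: 1024 Hz sampling, 20 s evaluation
records (10 s in the twenty-seed robustness sweep and some unit fixtures),
identification from 10 strikes of 2–4 s. The distortion-vs-$f_n$ trade-off
is summarized as the mean THD over a five-record cohort with cadences
1.7–2.3 steps/s: a single periodic record has a line spectrum whose
deterministic interference structure a very lightly damped resonance
($\xi = 0.01$, $Q = 50$) reads out as ripples of order 0.1 percentage point
on the THD floor, so the monotone trade-off is a property of the cohort
mean, exactly as such curves are read in practice.

## Known limitations

The whole approach stands on time-invariant linearity of the frame
transmission; a subject actively moving on the belt mass-loads the structure
and strictly violates it. Identification covers only bands the hammer
excites — the estimate is masked, never extrapolated, elsewhere. The
compensation is offline (non-causal by construction, zero-phase); no
real-time variant is provided. Only the vertical force component is
treated: shear components and center of pressure are out of scope, as are
voltage-level calibration and acquisition hardware.
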