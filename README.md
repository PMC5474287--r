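# grfcomp

Software force-treadmill compensation: reconstruct the vertical ground
reaction force (GRF) applied at a treadmill's track surface from the force
measured by load cells under its frame.

## The problem

Mounting an ordinary treadmill on four under-frame load cells makes an
*indirect* measurement force treadmill: the transducers see the force
transmitted through the resonant treadmill structure, not the GRF itself.
With the frame modeled as a second-order system of natural frequency
*f*<sub>n</sub> and damping ratio *ξ*, the transmission in the dimensionless
frequency *u* = *f*/*f*<sub>n</sub> is

|H(u)| = 1 / √((1 − u²)² + 4ξ²u²),  ∠H(u) = −atan(2ξu / (1 − u²)),

which is flat only for *u* ≪ 1. Since ~99% of walking vertical-GRF power
lies below ~12.75 Hz, a 45 Hz mount already overshoots the band edge by 8.7%
(|H(12.75/45)| ≈ 1.087). The hardware fix — stiffer, lighter frames with
*f*<sub>n</sub> of 160–219 Hz — is expensive. `grfcomp` implements the
software fix:

1. **Identify** the transmission transfer function Ĥ(f) = Y(f)/X(f) from
   impact-hammer strikes against a reference force platform on the track
   (single-strike spectral ratio, or H1 ensemble averaging with per-bin
   coherence over repeated strikes).
2. **Compensate** any later load-cell record by regularized inverse
   filtering, x<sub>c</sub>(t) = F⁻¹[Ĥ⁻¹(f) Y(f)], with Tikhonov
   regularization, band limiting at the 150 Hz acquisition cutoff, and
   separate static-component handling so body weight survives.
3. **Evaluate** fidelity with the THD metric — the energy of the estimation
   error relative to the energy of the true signal — plus the 98% bandwidth
   statistic and the bandwidth–THD correlation.

A synthetic-data generator (walk-on-the-spot GRF with heel-strike
transients, half-sine hammer pulses, multi-modal frame transmissions)
provides ground truth for every claim; see the methods vignette
(`vignettes/grf-compensation-methods.Rmd`).

## Worked example

```r
library(grfcomp)

model <- treadmill_model()              # synthetic 3-mode frame, modes 28/65/110 Hz
x  <- synth_walk_grf(gait_params(seed = 1))              # true GRF, 20 s @ 1024 Hz
y  <- apply_transmission(x, model, noise_sigma = 7, seed = 2)  # load-cell sum

trials <- make_identification_dataset(model, n_strikes = 10, record_s = 4,
                                      noise_sigma_y = 7, seed = 3)
tf <- estimate_transfer_h1(trials)      # phase 1: identify
xc <- compensate(y, tf, inversion_options())             # phase 2: compensate

thd(y, x)   # uncompensated distortion
thd(xc, x)  # after compensation
```

```
THD = 3.566% (energy ratio; sqrt convention 18.88%)
  error energy 400475 N^2 s / signal energy 1.12302e+07 N^2 s over 20 s
THD = 0.09588% (energy ratio; sqrt convention 3.097%)
  error energy 10767.9 N^2 s / signal energy 1.12302e+07 N^2 s over 20 s
```

The resonant frame distorts the walk record by 3.6% in error energy;
compensation with the transfer function identified from ten noisy strikes
reduces that ~37-fold, to under 0.1%. `run_pipeline(default_config(seed))`
wires the whole two-phase procedure together and writes signal CSVs, the
transfer function, a JSON metrics report and a log; the same steps are
scriptable from a shell via `inst/cli/grfcomp.R` (subcommands `simulate`,
`identify`, `compensate`, `evaluate`, `som-curves`, `run`).

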