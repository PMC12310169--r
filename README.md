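# magstim

Peripheral nerve stimulation (PNS) thresholds limit how hard the drive and
gradient coils of magnetic particle imaging (MPI) and MRI systems can be
switched. `magstim` is an R package for simulating and analysing
magnetostimulation threshold experiments with kilohertz-range sinusoidal
magnetic fields, built around a head-solenoid study design: 8 subjects,
16 stimulus frequencies from 200 Hz to 88.1 kHz, 256-cycle pulses with a
25-cycle exponential ramp-up, adaptive threshold titration, and
strength-duration-curve analysis. It is aimed at researchers who design PNS
safety experiments or need a fully testable stand-in for such data.

## What it computes

* **Coil field efficiency.** The layered solenoid winding is expanded into
  filamentary loops and its field per unit current, B_eff (µT/A), is
  computed from complete elliptic integrals at arbitrary (r, z).
* **Resonant-circuit pulse shaping.** The series RLC drive at resonance
  responds to a step sinusoid with current envelope
  `i(t) = I0 (1 − e^{−t/τ_nat}) sin(2πft + φ)`, `τ_nat = 2L/R`. Modulating
  the voltage envelope as
  `v(t) = V0 (1 − (τ_des − τ_nat)/τ_des · e^{−t/τ_des}) sin(2πft)` enforces
  a common desired ramp-up `τ_des` (25 cycles) at every frequency. The
  package synthesises these waveforms, integrates the circuit ODE, and
  fits current traces for (I0, τ, f, φ).
* **Psychometric titration.** A subject's probability of reporting a
  sensation at peak field B follows the sigmoid
  `g(B) = 1/(1 + e^{−(B − B_th)/B_width})`. The titration protocol (coarse
  ~5/10 mT ascent, then a fine staircase at 1/80th of the initial
  estimate) is simulated against virtual subjects and `(B_th, B_width)`
  estimated by maximum likelihood.
* **Censoring-aware population averaging.** Subjects whose thresholds
  exceed the amplifier ceiling are right-censored; per-frequency means and
  SDs come from fitting the Gaussian CDF to the empirical fraction
  stimulated (least squares), with a censored maximum-likelihood
  cross-check.
* **Strength-duration analysis.** The hyperbolic SDC
  `B_th(f) = B_rheo (1 + 1/(2 τ_chron f))` is fitted to low-frequency
  means; thresholds are rescaled from constant cycle count to constant
  pulse duration with the empirical law
  `B_norm(T) = 1 + 0.44 e^{−(T/4.32 ms)^{0.60}}`, and expressed against the
  IEC effective stimulus duration `t_eff = 1/(πf)`.
* **Synthetic cohorts.** Ground-truth subject curves combine the
  hyperbolic SDC with a smooth high-frequency rise (minimum near 20 kHz,
  ~39% increase from 25.3 to 88.1 kHz), lognormal inter-subject spread,
  and per-frequency amplifier ceilings, so the entire pipeline is testable
  without any external data.

## Worked example

```r
library(magstim)
pl <- run_pipeline(seed = 7)
print(pl)
#> PNS pipeline (seed 7)
#>   threshold minimum at 16.9 kHz
#>   SDC (f <= 10000 Hz): B_rheo = 4.51 mT, tau_chron = 389 us
#>   vs 49 kHz: +15.4%, p = 0.1134 (scaled p = 0.3111)
#>   vs 66.7 kHz: +26.1%, p = 0.01601 (scaled p = 0.09255)
#>   vs 88.1 kHz: +22.0%, p = 0.004504 (scaled p = 0.1379)
```

The simulated cohort reproduces the qualitative study headline: pooled
thresholds fall with frequency, reach their minimum between 16.9 and
25.3 kHz, and rise again towards 88.1 kHz — a significant increase by the
independent-samples t-test — while the hyperbolic SDC fitted below 10 kHz
under-predicts every threshold above 49 kHz. A slice of the per-frequency
population table:

```r
pop <- pl$population
pop[pop$frequency_hz %in% c(700, 8050, 16900, 25300, 88100), c(1, 2, 3, 4, 6, 8)]
#>  frequency_hz mean_mt sd_mt cv_percent n_censored mean_scaled_mt
#>           700   11.30 0.739       6.54          5          11.30
#>          8050    5.35 1.008      18.84          0           5.27
#>         16900    4.96 0.942      18.99          0           4.72
#>         25300    5.05 0.971      19.24          0           4.66
#>        88100    6.43 0.738      11.48          5           5.36
```

`n_censored` counts subjects whose thresholds exceeded the amplifier
ceiling at that frequency (the ceilings bind at 600 Hz, 700 Hz and
88.1 kHz, as in the study design); `mean_scaled_mt` is the mean rescaled
to infinite pulse duration.

Individual stages are available directly, e.g.

```r
field_at(build_loop_stack(coil_geometry()), r = 0, z = 0)
#> field sample at (r = 0 m, z = 0 m): 222.5 uT/A (Br = 0.00, Bz = 222.53)

scale_to_duration(5.11, pulse_duration(25300))  # 4.72 mT at infinite duration
```

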