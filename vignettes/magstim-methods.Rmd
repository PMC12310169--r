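---
title: "Methods: simulating and analysing magnetostimulation thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing magnetostimulation thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magstim)
```

`magstim` models a head-solenoid peripheral nerve stimulation (PNS)
threshold experiment end to end: the coil's magnetostatics, the resonant
drive circuit and its pulse shaping, the psychometric titration of
per-subject thresholds, censoring-aware population averaging, and
strength-duration-curve (SDC) analysis. This vignette records the models,
their assumptions, and the numerical and design choices, in the order the
pipeline uses them.

## Coil field model

The winding (3 layers × 18 turns of 4 mm wire, 11 cm long, 27 cm inner
winding diameter by default) is replaced by filamentary circular loops at
the wire centres. The field of each loop is evaluated with complete
elliptic integrals (`pracma::ellipke`); on the axis this reduces exactly to
the closed form $\mu_0 a^2 / 2(a^2+z^2)^{3/2}$. Efficiency is reported as
the per-ampere field magnitude $|B|$, matching what a three-axis
magnetometer measures.

Two conventions are not fixed by a winding's printed summary, and both are
configurable:

* **Layer radii.** The inner winding diameter is taken to name the inner
  surface of the first layer's wire, so layer $k$ sits at radius
  $D_{in}/2 + d_w/2 + k\,d_w$ (0.137/0.141/0.145 m for the default coil).
* **Axial spacing.** Eighteen close-wound 4 mm turns would span only
  72 mm, inconsistent with the stated 110 mm length, so the turns are
  spread evenly with their centres spanning the full coil length. The
  alternative (centres spanning $L(1 - 1/n)$, i.e. pitch $L/n$) changes
  the central efficiency by under 1%; the full-span convention is the
  default.

The filament approximation ignores the current distribution inside the
hollow conductor, eddy currents, and proximity/skin effects; these are
below the few-percent level relevant at the coil centre but grow towards
the windings, which is why off-centre comparisons against distributed-
current (finite-element) references should be read with a wider band.

## Circuit model and pulse shaping

The tuned drive is a series RLC circuit; untuned, a series RL. At
resonance a step-sinusoid voltage produces a current envelope
$1 - e^{-t/\tau_{nat}}$ with $\tau_{nat} = 2L/R$. Because $R$ varies
between capacitor-bank settings, the envelope of the *voltage* is
pre-compensated,

$$v(t) = V_0\left(1 - \frac{\tau_{des}-\tau_{nat}}{\tau_{des}}
  e^{-t/\tau_{des}}\right)\sin(2\pi f t),$$

which yields a current ramp with the desired constant $\tau_{des}$
(25 cycles by default, chosen above the largest natural constant so the
required envelope never overshoots $V_0$). Untuned conditions apply the
plain envelope $1 - e^{-t/\tau_{des}}$ directly; at the sub-kilohertz
frequencies involved, the RL transient ($L/R \sim$ 0.4 ms) is negligible
against $\tau_{des} \geq$ 36 ms.

Numerical choices:

* **Integration** uses classical fixed-step 4th-order Runge–Kutta at the
  trace sampling rate (256 samples per cycle by default, 64 minimum).
  Since the ODE is linear, the per-step RK4 update is an affine map whose
  matrices are precomputed once — algebraically identical to stepwise RK4
  but fast in R. The test suite checks the integrator against
  `deSolve::lsoda` at tight tolerances.
* **Waveform fitting** is Levenberg–Marquardt least squares
  (`minpack.lm::nlsLM`) of $I_0(1-e^{-t/\tau})\sin(2\pi f t + \phi)$, with
  starting values taken from the trace itself: frequency from
  zero-crossing counts, amplitude and phase from a quadrature regression
  on the steady-state tail, and $\tau$ from a log-linear fit of the
  per-cycle envelope. The fit needs the trace to cover roughly three
  ramp-up constants; fitted phase is reported in $(-\pi, \pi]$ with
  current lagging voltage in untuned conditions.
* **Steady-state voltage amplitude** (for the series-resistance ratio
  $R_{series} = V_{0,fit}/I_{0,fit}$) is fitted on the final quarter of
  the samples; the frequency entering that quadrature regression comes
  from linearly interpolated zero-crossing times, since over tens of
  cycles even a 1% frequency error dephases the regressors.
* **Inductance.** $L$ is not part of the coil's printed summary. The
  default $L = 0.87$ mH is the least-squares value of
  $1/((2\pi f_{res})^2 C)$ over the high-frequency capacitor/resonance
  pairs; the implied $L$ drifts at the lowest bank settings (possibly a
  bank reconfiguration), so the low-frequency resonances of
  `tuned_bank()` are taken from the model, not asserted against printed
  stimulus frequencies.
* **Per-setting resistance.** The per-condition series resistances are
  not published. Defaults interpolate the natural ramp-up, in cycles,
  log-linearly in frequency between the two known anchors (12.7 cycles at
  4.04 kHz and 22.3 cycles at 35.4 kHz), clamped outside, and set
  $R = 2Lf/\tau_{cycles}$. This spans a realistic range while keeping
  $\tau_{nat} < \tau_{des}$ everywhere.

## Psychometric threshold estimation

A subject's response to a pulse of peak amplitude $B$ (mT at the coil
centre) is Bernoulli with probability
$g(B) = (1 + e^{-(B - B_{th})/B_{width}})^{-1}$. `fit_sigmoid()` maximises
the likelihood over $(B_{th}, \log B_{width})$ (Nelder–Mead). Titration
data are frequently *perfectly separable* — every non-response below every
response — where the unpenalised MLE diverges ($B_{width} \to 0$). Such
fits return the midpoint of the separating gap with
$B_{width} = \max(\text{floor}, \text{gap}/4)$ and a `separation_flag`.
The width floor defaults to a tenth of the fine titration step. A tiny
ridge on $1/B_{width}$, scaled by the amplitude spread so estimates are
unit-equivariant, stabilises near-separable fits; at its default weight
($10^{-6}$) it is numerically invisible on well-conditioned data.

`run_titration()` follows the experimental protocol: a coarse upward ramp
(10 mT steps below 1 kHz, 5 mT above, starting one step up from zero)
until the first reported sensation, then an up/down staircase with step
$\hat B_{th,0}/80$, refitting the sigmoid after every response (24
staircase pulses by default; the study's runs suggest roughly 10–30).
The staircase rule itself is not specified in the source protocol; the
simple "one fine step down after a sensation, up after none, centred on
the running estimate" rule is used because it is the standard up/down
method and keeps the estimate bracketed. Two boundary rules matter:

* A run whose every sensation occurred at the amplifier ceiling is
  *censored* at the ceiling — the threshold itself is at or above the
  maximum output. Censoring is an outcome, not an error.
* A staircase that never collected a non-response (threshold below the
  lowest amplitude visited) is extended downward until it brackets the
  threshold, as an experimenter would.

Interim staircase refits use relaxed optimiser settings (they only steer
the next amplitude); the final estimate is refitted at full precision.

## Population averaging under censoring

Per-frequency thresholds across subjects are modelled as Gaussian.
With right-censoring at the amplifier ceiling, the default estimator fits
$\Phi((B-\mu)/\sigma)$ by least squares to the empirical cumulative
fraction stimulated, evaluated at the observed thresholds with Hazen
plotting positions $(i - 1/2)/n$ (the `ecdf` convention $i/n$ is also
exposed); censored subjects enlarge the denominator $n$ but contribute no
point. A right-censored Gaussian maximum-likelihood estimator is provided
as an independent cross-check route, and the two agree in the uncensored
limit, where both also agree with the sample moments. An SD floor of
$10^{-3}$ mT keeps degenerate (all-equal) tables well defined.

With only two or three observed thresholds out of eight the fit is close
to unidentifiable; the pipeline reports undetermined (NA) moments for a
frequency whenever fewer than two thresholds were observed or the fitted
mean is unphysical, rather than propagating a meaningless number. Note
that with $n = 8$ subjects the statistical information is modest under
*any* estimator: at ~5/8 censoring the standard error of the recovered
mean is comparable to half the population SD.

Comparisons between frequencies use the two-sided independent-samples
t-test (Student pooled-variance by default, Welch optional). In the
pipeline's high-frequency contrasts, censored subjects enter at their
ceiling amplitude — a lower bound on their threshold. Because censoring
occurs in the *higher* group, this substitution is conservative for
detecting a threshold increase. Test-retest agreement is summarised the
standard Bland–Altman way: mean difference and mean ± 1.96 sample SD of
the differences.

## Strength-duration analysis

The hyperbolic SDC $B_{th}(f) = B_{rheo}(1 + 1/(2\tau_{chron} f))$ is
fitted by unweighted nonlinear least squares to the pooled means at
frequencies at or below a 10 kHz cutoff (the regime where the hyperbolic
model is conventionally valid), initialised at
$B_{rheo} = \min \bar B_{th}$, $\tau_{chron} = 200\ \mu$s. Residuals are
reported at all frequencies so high-frequency deviations are visible.
Plotted against the IEC effective duration $t_{eff} = 1/(\pi f)$ the
hyperbola is the straight line
$B_{rheo} + (B_{rheo}\pi/2\tau_{chron})\,t_{eff}$. The generic numeric
$t_{eff}$ operator locates the first two waveform extrema by sign changes
of the discrete derivative with a relative plateau tolerance (default
$10^{-3}$), then divides the peak-to-peak amplitude by the maximum slope
between them.

Pulse-duration rescaling uses the empirical law
$B_{norm}(T) = 1 + \alpha e^{-(T/\beta)^\gamma}$ with $\alpha = 0.44$,
$\beta = 4.32$ ms, $\gamma = 0.60$; $T$ is strictly in milliseconds at
this interface. Rescaling composes exactly:
$A \to B \to C$ equals $A \to C$.

## The synthetic cohort

The generator defines the study conditions under which everything is
tested:

* **Population curve.** $B(f) = B_{rheo}(1 + 1/(2\tau_{chron}f)) \cdot
  (1 + a \max(0, \ln(f/f_k))^q)$ with $B_{rheo} = 4.4$ mT,
  $\tau_{chron} = 405\ \mu$s, $f_k = 16.9$ kHz, $q = 2$ and $a = 0.176$.
  The multiplicative log-power rise is an artifact choice (the literature
  offers candidate mechanisms — sodium-channel time constants, potassium
  permeability, beta dispersion — but no equation); it is smooth,
  two-parameter, and reduces to the pure hyperbolic SDC at $a = 0$.
  With $q = 2$, $a$ solves $B(88.1\,\text{kHz})/B(25.3\,\text{kHz}) =
  1.39$ in closed form, and the curve's minimum falls near 20 kHz,
  between the 16.9 and 25.3 kHz study frequencies.
* **Subjects.** Subject $i$'s curve is the population curve times a
  lognormal factor (median 1, CV 0.15 — inside the 9–23% range of
  observed cross-subject spreads); thresholds stay positive and the
  factor is shared across frequencies, as subject-level susceptibility
  plausibly is. The sigmoid width is 3% of the local threshold.
* **Ceilings.** Amplifier limits are finite only where the study design
  saw censoring: the population lognormal 75th percentile at 600 Hz and
  40th percentile at 700 Hz and 88.1 kHz (expected censoring 2/8 and
  5/8), infinite elsewhere. They are fixed at specification time.
* **Randomness.** One master seed; every (subject, frequency, run)
  titration draws from its own derived stream, so any single run is
  reproducible in isolation. Retest runs draw fresh streams from the same
  true curve, with no drift term.

What the generator does *not* emulate: the true shape of individual
threshold curves between the sampled frequencies (unknowable from
published means), audible-vibration confounds below 8 kHz,
reaction-time or attention effects, and any demographic structure. Tests
that pass against this cohort therefore validate the estimation pipeline
under the stated statistical structure — not the biology.

## Problem sizes and runtime choices

Simulated pulses use 256 cycles at 256 samples per cycle (65,536 samples
per trace) for circuit runs; waveform-fit Monte-Carlo uses 100-cycle
traces at 128 samples per cycle over 100 replicates. The end-to-end
synthetic replication runs the full pipeline over 100 master seeds, each
with 8 subjects × 16 frequencies plus 10 retest runs. Parameter-recovery
studies use 200 replicates (population and SDC fits). These sizes put
Monte-Carlo standard errors comfortably below the tolerances being
asserted while keeping the whole suite in the minutes range.

## Known limitations

* The published per-subject dataset lives in the original authors'
  repository and is not consumed here; the published fit values
  (rheobase 6.27 mT, chronaxie 405 µs) and reported p-values (0.011,
  0.053, 0.025) can only be checked against that data, as an optional
  external exercise. The package's own calibration targets are the
  printed mean thresholds and their arithmetic.
* The filament field model deliberately excludes finite-element
  conductor detail; expect percent-level agreement at the coil centre
  and larger deviations near the windings.
* The censored population fit is honest about small-$n$ limits: with
  5 of 8 subjects censored no estimator recovers the population mean to
  a fraction of the population SD with high per-cohort probability.
* The hyperbolic SDC is used as a *reference model*; the package's own
  synthetic truth deviates from it above the knee frequency by
  construction, which is precisely the effect the analysis is designed
  to expose.
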