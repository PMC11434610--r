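---
title: "Modelling terahertz enhancement of potassium conductance in a cortical neuron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling terahertz enhancement of potassium conductance in a cortical neuron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thzneuron)
```

## The model

Resonant absorption of ~36 THz photons by voltage-gated potassium channels
increases potassium conductance approximately linearly with the field
intensity, while sodium conductance is essentially unaffected. `thzneuron`
represents this effect in a single-compartment conductance-based neuron:

$$C\frac{dv}{dt} = G_{stim} - s_{Na}\,\bar g_{Na} m^3 h (v - v_{Na})
  - s_K\,\bar g_K n^k (v - v_K) - I_{leak},$$

with $C = 0.75\ \mu F/cm^2$ and gating kinetics
$dy/dt = \alpha_y(v)(1-y) - \beta_y(v)\,y$ for $y = m, n$. The inactivation
gate relaxes toward the fixed steady state
$h_\infty(v) = 1/(1+\exp((v+60)/6.2))$ with time constant
$1/(\alpha_h+\beta_h)$. The stimulating field
$E(t) = A\,u\cos(\omega t + \phi)$, $\nu = \omega/2\pi \approx 36$ THz, has a
period (~28 fs) ten orders of magnitude below membrane time scales, so it
enters the model *only* through its time-averaged intensity via the scale
factors

$$s_K = 1 + \beta_K I, \qquad s_{Na} = 1 + \beta_{Na} I \ (\beta_{Na} = 0
\text{ by default}),$$

never as an oscillatory drive. Intensity is in model-relative units and
$\beta_K$ is a calibration parameter: operating points are defined by model
output (e.g. "the scaling at which firing falls to 30% of control"), not by
a physical field value.

## Design choices in the membrane equation

Two aspects of the equation admit more than one reading, and the rate
functions $\alpha_y, \beta_y$ must be chosen. All are configurable; the
defaults were fixed by what the model can and cannot do, measured with this
package:

**K gate exponent and leak form.** The K⁺ current may use $n^1$ or the
classical $n^4$, and the leak may be gated ($g_L n (v - v_L)$) or ohmic
($g_L (v - v_L)$). All four combinations are implemented behind
`hh_params(k_gate_exponent =, leak_gated =)`. With first-power K gating at
the default conductances the membrane is not excitable — the linear-in-$n$
K current is so strong at subthreshold voltages that no constant drive (up
to 200 µA/cm² tested) produces repetitive firing. The default is therefore
$n^4$ with an ohmic leak, and the headline sweep
(`variant_operating_summary()`) always evaluates the full 2×2 grid and
reports every variant.

**Rate-function family.** Two families are provided
(`hh_params(rate_set =)`). The classic squid-axon rates make the model
type II excitable: as potassium conductance is scaled up under constant
drive, the firing rate falls only to roughly 55–75% of control and then
stops abruptly. A graded ~70% rate reduction — the behaviour this model
exists to study — is unreachable in that family. The Traub–Miles cortical
pyramidal family is type I (firing rate continuous down to zero), matches
the cortical setting, and is the default. Each family carries its canonical
maximal conductances and reversal potentials (traub: $\bar g_{Na} = 100$,
$\bar g_K = 80$, $g_L = 0.1$ mS/cm², $v_{Na} = +50$, $v_K = -100$,
$v_L = -67$ mV; classic: 120/36/0.3 and +50/−77/−54.4), all overridable.

**Integration.** Fixed-step 4th-order Runge–Kutta (compiled), default
$dt = 0.01$ ms. Gates are clamped to $[0,1]$ each step (RK4 can overshoot by
$O(dt^5)$). The test suite verifies step-halving convergence of spike times
(0.01 vs 0.005 ms within 0.05 ms over 500 ms) and agreement with an
independent adaptive integrator (`deSolve::lsoda` at tolerance $10^{-9}$) on
the same right-hand side. Integration failure raises an error naming the
divergence time.

**Initial state.** `resting_state()` scans $[-110, -30]$ mV for
zero-current equilibria with gates at steady state and returns the most
hyperpolarized *stable* one (eigenvalues of a finite-difference Jacobian of
the full 4-dimensional system); if none is stable, the most hyperpolarized
root.

## The headline sweep and its calibration

`variant_operating_summary()` reproduces the simulation study's two summary
numbers. For each variant it:

1. finds the repetitive-firing (DC) threshold by bisection
   (`dc_firing_threshold()`), scanning upward first because very strong
   drive can silence the model through depolarization block;
2. drives the neuron at 1.07× that threshold and sweeps
   $s_K \in [1, 3]$ in steps of 0.01, measuring at each point the
   steady-state firing rate and the FWHM of a representative (median)
   steady-state action potential;
3. reports the FWHM percentage of control at the grid point where the rate
   ratio is nearest 0.30, and the rate reduction at the grid point where
   the FWHM ratio is nearest 95%.

Two calibration choices deserve explanation:

- **Drive at 1.07× threshold.** A pure potassium-conductance increase can
  silence firing only when the neuron operates near its threshold; far
  above it, spike-shape changes saturate long before the rate moves. At
  1.07× threshold the control model fires ~9 Hz, a typical low cortical
  rate, and the sweep passes through the joint operating point (FWHM ≈ 95%
  of control *and* rate ≈ 30% of control at the same scale factor,
  $s_K \approx 1.13$). This near-rheobase regime is the one in which the
  modelled effect exists at all.
- **Steady-state window of 4.5 s (of a 5 s run).** Firing rates are spike
  counts over a window; at ~9 Hz a 400 ms window quantizes the rate in
  2.5 Hz steps, i.e. ~25-percentage-point steps in the reported reduction.
  The 4.5 s window reduces the quantum to 0.22 Hz while keeping the full
  four-variant sweep around a minute of CPU. The integrator-convergence
  check keeps its own 500 ms duration.

## Action-potential metric conventions

The source conventions are not fully standardised across laboratories, so
they are explicit parameters here:

- **Spike**: upward crossing of 0 mV followed by a local maximum; minimum
  peak separation 2 ms.
- **AP threshold**: first sample of the contiguous upstroke on which
  $dv/dt \ge 20$ mV/ms (configurable).
- **FWHM / half-width** (one computation, two common names): time above the
  midpoint between baseline and peak, with linearly interpolated crossings.
  The default baseline is the AP threshold voltage; a resting-potential
  baseline is available (`ap_features(baseline = "rmp")`). The headline
  sweep uses the threshold baseline and reports it.
- **Rheobase**: smallest 30 ms pulse amplitude eliciting ≥ 1 spike, by
  bisection (tested against exhaustive grid search).
- **Steady-state rate**: spike count over the window after discarding the
  initial transient.

## Voltage-clamp analysis

`make_protocol()` encodes the three step protocols (Nav: −80…−10 mV from a
−100 mV command; Kv: −70…+130 mV, 100 ms; K_Leak: −120…−30 mV, 400 ms,
−70 mV command; step increment 10 mV by default). Synthetic currents come
from closed-form exponential gate relaxation (the command voltage is
piecewise constant), so generator ground truth is exact. Choices:

- Kv I–V values use the steady-state mean over the last 20% of the step;
  Nav uses the signed peak. Both modes are available in `iv_curve()`.
- Activation curves are normalized by the *fitted* $g_{max}$, not the
  largest data point (robust to noise).
- Boltzmann fits ($1/(1+\exp(\pm(V_{1/2}-V)/k))$, bounds
  $k \in (0.1, 50)$ mV) are initialised from a logit-linear regression of
  the normalized response on voltage; a coarse midpoint heuristic is the
  fallback. The logit start is used because Levenberg–Marquardt from the
  coarse start intermittently lands in a step-function local minimum on
  noisy data.
- The leak rule: only steps at or above −65 mV enter the leak line fit
  (slope = conductance, V-intercept = reversal). On the kleak preset this
  is exactly the four levels −60…−30 mV.
- Pharmacological isolation is represented only as "one channel type per
  synthetic set"; no blocker arithmetic is modelled.

## Extracellular unit pipeline

The pipeline starts from sorted unit waveforms and spike times (spike
sorting itself is out of scope). Features are the trough-to-peak duration,
the trough-lobe half-width (both from `waveform_features()`, crossings
interpolated) and the mean rate. Classification is either the fixed
430 µs trough-to-peak rule (wider ⇒ putative pyramidal cell) or 2-means
clustering on the standardized feature triplet with 10 restarts and a fixed
seed; the cluster with the larger mean trough-to-peak is labelled PYR (ties
broken against the 430 µs rule). Rate changes are called per unit from
1 s binned counts with a two-sided Wilcoxon rank-sum test at
$\alpha = 0.05$ (bin width and level configurable; the binning is a
convention, not a measured value), direction by the sign of the median
count difference.

## What the synthetic generator does and does not emulate

`gen_unit_population()` draws: trough-to-peak durations from two Gaussian
modes straddling the 430 µs boundary (600 µs PYR / 250 µs INT, sd 60 µs);
half-widths and baseline rates differing by class (PYR slower); and a
direction label per unit — decreased (×0.5 post rate), increased (×2) or
unchanged — with condition-specific default fractions (sham:
63.4/10.8/25.8%; SNI: 61.8/20.3/17.9%). Labels are allocated by
largest-remainder rounding of the configured fractions and then shuffled,
so the realised population fractions equal the configured ones at any
population size. Spike trains are Poisson with a 2 ms dead time; epochs are
300 s by default. Every generator is a pure function of (configuration,
seed) and emits ground truth alongside the data.

The generator deliberately does **not** emulate: bursting or other
non-Poisson spiking statistics, rate drift within an epoch, waveform
non-stationarity or sorting contamination, correlated activity across
units, or continuous raw voltage. Passing recovery tests on this generator
therefore demonstrates correctness of the analysis chain under its stated
statistical assumptions, not robustness to every property of real
recordings.

## Problem sizes used by the tests

The packaged checks run the four-variant sweep at the 0.01 grid over 5 s
simulations (~1 minute), 200-replicate Boltzmann recovery at noise
sd 0.02, a 1000-unit classifier-agreement comparison, 1000 null and 100
powered rate-change simulations at 60 bins, and the full 108-unit
population round trip at 300 s epochs.

## Known limitations

- Single compartment, no synaptic input, no network context, no thermal
  effects of the field; the blue-light control corresponds to zero
  conductance modulation and is not modelled further.
- The conductance-scaling law is linear by construction; saturation at
  high intensity is not represented.
- The first-power K-gate variants are retained for completeness but are
  not excitable at the default conductances.
- Statistics across animals or groups are out of scope; all inference here
  is per-unit or parameter recovery on synthetic data.
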