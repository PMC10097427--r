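---
title: "Modelling light-evoked Kv1.3 currents on organic photocapacitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling light-evoked Kv1.3 currents on organic photocapacitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oepcsim)
```

Organic electrolytic photocapacitors (OEPCs) are thin-film devices that
convert millisecond light pulses into capacitive extracellular currents.
When a cell adheres to the device, those currents polarise the thin
electrolyte cleft under the attached membrane and can gate voltage-dependent
channels.  `oepcsim` implements the complete modelling chain needed to
analyse whole-cell patch-clamp recordings of such stimulation: a Markov
model of the Kv1.3 channel, the whole-cell recording circuit, a two-domain
model of the stimulated cell, the inversion that expresses a measured
current as an equivalent command voltage, conductance–voltage analysis, and
the estimation procedures that fit the model to data.  A synthetic-data
generator stands in for the recordings, so every stage runs and is tested
without any external data.

## The gating model

Kv1.3 gating is a sequential hidden-Markov chain with four closed states and
one open state,

$$C_0 \rightleftharpoons C_1 \rightleftharpoons C_2 \rightleftharpoons C_3
  \rightleftharpoons O,$$

with voltage-dependent rates between closed states,
$\alpha(V) = \alpha_1 e^{V/m}$ forward and $\beta(V) = \beta_1 e^{-V/n}$
backward, and a voltage-independent pair $A$ (opening, $C_3 \to O$) and $B$
(closing).  The slope voltages $m = RT/(\alpha_2 F)$ and $n = RT/(\beta_2 F)$
absorb temperature and the gating charge.  The fitted parameter set shipped
as `kv13_rates()` is

```{r}
unlist(kv13_rates()[1:6])
```

The source text counts "four closed states" while indexing them
$C_i, i = 0,\dots,4$; we resolve this in favour of the count — four closed
states plus the open state — and place the voltage-independent $A/B$ pair on
the final $C_3 \rightleftharpoons O$ transition, consistent with the
description of $A$ as the forward rate *to the open state*.  The chain
length is configurable (`rate_params(n_closed = )`) so the five-closed-state
alternative remains testable; no Hodgkin–Huxley subunit multiplicities
(4$\alpha$, 3$\alpha$, …) are applied because the model defines uniform
rates.  Temperature defaults to 293.15 K (room-temperature recordings).

The macroscopic current is $I = N g\, p_O (V - E_K)$ with the measured
reversal potential $E_K = -73$ mV.  The single-channel conductance $g$ is
not reported; we default to a nominal 12 pS.  Only the product $N g$ is ever
compared with data and the per-cell fit of $N$ absorbs $g$, so this choice
is a unit convention, not a claim.  With the default $N = 12000$ the maximal
whole-cell conductance is $\approx 0.82 \cdot 144\,\mathrm{nS}$, of the same
order as the conductance reported for a strongly expressing cell.

## The recording circuit

The whole-cell voltage-clamp model is

$$C_M \frac{dV}{dt} = \frac{V_C - V}{R_S} - G_B (V - E_{VHEK})
  - I_{Kv1.3}(t, V), \qquad
  I_{out} = \frac{V_C - V}{R_S} + \frac{V_C}{R_{seal}},$$

with an ideal amplifier (no dynamics, no series-resistance compensation —
access resistance is deliberately part of the model, matching uncompensated
recordings) and the seal current flowing from the pipette node to the bath.
In current clamp (I = 0) the amplifier is an ideal voltage follower: the
pipette carries no current and the seal leak is neglected, so the resting
potential equals the leak equilibrium exactly.  Defaults: $C_M$ = 20 pF,
$R_S$ = 8 MΩ, $R_{seal}$ = 4 GΩ, $R_B$ = 1 GΩ, $E_{VHEK}$ = −40 mV
(HEK293 cells rest near −40 mV).

The acquisition chain is a causal fourth-order Bessel low-pass at 2 kHz.
Because no installed filter-design routine provides an analog Bessel
prototype, the package derives it from the reverse Bessel polynomial,
normalises the cutoff to the −3 dB point (the convention in which
electrophysiology amplifiers state their filter corner), and discretises by
impulse invariance.  Impulse invariance aliases a small amount of DC gain
(≈0.04 % at 50 kHz, ≈1 % at 10 kHz); the discrete numerator is rescaled to
exact unity DC gain so that steady-state currents are never biased by the
sampling rate.  Tests verify the discrete impulse response against an
independent continuous-time solution of the analog filter ODE.

## The two-domain stimulation model

The membrane is split into the attached domain (area $A_J$, facing the
cleft at potential $V_J$) and the free domain (area $A_{MJ} = A_M - A_J$,
facing the grounded bath).  Each domain carries area-proportional shares of
the membrane capacitance, the background conductance and the channel
population (uniform density — no redistribution is reported), and each
domain's gating is driven by its own membrane voltage ($V_I - V_J$
attached, $V_I$ free).  The cleft drains to the bath through the seal
resistance $R_J$; the photostimulus enters the cleft node either as a
prescribed source voltage behind the electrode capacitance $C_E$ or as an
injected photocurrent.  The printed domain equations contain two evident
typographical slips — the attached-membrane equation carries the free area
on its capacitive term and the free-membrane conductance on its channel
term; dimensional and symmetry consistency require $A_J$ and
$G_{M,attached}$ there, and that is what is implemented.  Likewise the
capacitance multiplying areas must be the specific capacitance, so the
stored total $C_M$ is divided by $A_M$.

The attached fraction defaults to the measured median 27.36 %.  $R_J$ and
$C_E$ are not reported; we default to $R_J$ = 10 MΩ (typical of
cell–substrate seals in two-domain modelling) and $C_E$ = 1 µF/cm² scaled by
the attached area, both configurable and echoed in all outputs.  The device
back electrode is floating; the return path is through the bath, which is
how the circuit is wired here.

### Equivalent clamp voltage

`equivalent_clamp_voltage()` answers: what command-voltage waveform would
reproduce a measured current in the circuit *without* any cleft stimulus?
At each sample the output relation is inverted algebraically for $V_C$ and
the membrane state is advanced under the recovered drive, using the same
discrete scheme as the forward simulation — so feeding back a simulated
(unfiltered) current reproduces its command waveform to machine precision,
and the round trip is tested at 0.1 mV RMS.  The inversion operates on the
unfiltered output relation by default; a `defilter` switch inverts the
discrete Bessel filter first for use on filtered recordings, at the price of
amplified high-frequency noise.

## The photostimulus generator

The synthetic stimulus is biphasic, cathodic-leading and charge-balanced:
the device first drives the cleft negative (which *depolarises* the attached
membrane, since $V_{M,att} = V_I - V_J$), then returns the accumulated
charge after light-off.  Two representations are implemented.  The
voltage-source form (a source charging to $-V_0$ with time constant
$\tau_{on}$ behind $C_E$) couples purely capacitively: with millisecond
charging constants it polarises the cleft only during $\sim R_J(C_E + C_a)$
≈ 0.1 ms transients.  The recordings, however, show a *sustained*
conductance increase throughout the 5 ms pulse, and the printed
equivalent-voltage waveform has a sustained plateau between its two peaks.
The generator therefore defaults to the photocurrent form: an injected
cleft current charging exponentially toward a cathodic plateau
($\tau_{on}$ = 0.5 ms), followed by an anodic discharge that returns exactly
the accumulated charge ($\tau_{off}$ = 2 ms).  The 2 ms discharge constant
keeps the off-transient a small multiple of the plateau, matching the ratio
visible in the printed equivalent-voltage extrema; a 0.5 ms discharge would
make it nine-fold.  Charge balance holds to < 0.1 % by construction and is
tested.

Peak amplitude maps to light intensity through a saturating curve,
$I_0 = I_{max}\,\phi/(\phi + \phi_{1/2})$ with $\phi_{1/2}$ = 4 mW mm⁻²;
$I_{max}$ = 4.5 nA is calibrated once so that the default cell sees
attached-membrane deflections of ≈30 mV at 13 mW mm⁻², the net shift the
study attributes to its strongest intensity.  These constants are explicit
configuration values, not claims about device physics.

## Numerical scheme

The coupled gating/circuit systems are stiff: the fastest gating relaxation
is $1/(A+B) \approx 18$ µs against sweep durations of seconds.  The compiled
integrator advances each output interval (optionally substepped to at most
`h_max` = 20 µs) by Lie splitting: the gating vector is propagated by the
*exact* matrix exponential of the generator at the frozen membrane voltage
(a specialised 5×5 scaling-and-squaring routine), then the node voltages by
the exact solution of the linear circuit equations with conductances frozen
(an augmented-matrix exponential).  The coupled steady state is an exact
fixed point of both half-steps, so equilibria are preserved; with channels
disabled the scheme is exact, which is why the passive RC transient matches
its closed form to machine precision.  An independent adaptive path
(`deSolve::lsoda` on the same equations, rtol 1e−8 and tighter in tests)
cross-checks the fixed-step scheme; agreement is asserted at 0.1 mV or
better away from stimulus discontinuities.  A sampled stimulus smears its
jump discontinuity (light-off in the photocurrent mode) across one grid
interval — the cross-check excludes a few samples around the edges for this
reason, and simulations of pulsed stimuli should use sampling rates well
above the filter Nyquist bound (the analyses here use 25 kHz).

Two-domain simulations start from the coupled $(V_I, V_J)$ equilibrium
(fixed-point iteration on the node equations with gating at steady state),
so pre-stimulus baselines are flat to solver precision.  Probability
conservation is enforced at 1e−9 at every output instant.  Exponential
arguments beyond |700| raise an error rather than overflow.

## Estimation

`fit_gating_parameters()` follows the study's hybrid strategy: a global
particle-swarm search (constriction coefficients, swarm 200 at study scale,
40 in the scaled-down runs; seeded and fully reproducible) inside the
parameter box, followed by local refinement.  The printed bound vectors are
garbled in the source (the upper bound renders with a merged token, and the
fitted $B$ would violate its natural reading); the default box
$[\alpha_1: 100\!-\!500,\ m: 0.01\!-\!0.5,\ \beta_1: 90\!-\!200,\
n: 0.1\!-\!1,\ A: 2000\!-\!50000,\ B: 1500\!-\!20000,\ N: 8000\!-\!20000]$
is a reconstruction that contains the fitted values, enforced at
construction and fully overridable.  For the local stage this package uses
Levenberg–Marquardt on the stacked current-residual vector in log-parameter
space rather than a scalar quasi-Newton method: the objective valley is
extremely anisotropic (see below) and only a residual-vector method
converges through it.  The swarm objective is the pointwise sum of squared
current residuals across all sweeps — the study does not state its exact
objective, and pointwise SSE is the natural reading.  Candidate simulations
use the same grid step as the targets so discretisation bias cancels.

`fit_channel_count()` minimises the quadratic *relative* difference between
steady-state current simulations (self-consistent circuit equilibrium) and
measurements over steps above a 20 pA floor, averaging the last 10 % of the
step as "steady state" (the averaging window is not stated in the source).
`fit_patch_parameters()` refines $(R_B, C_M, R_S, R_{seal})$ against
sub-threshold activation sweeps; a known channel model can be included in
its candidate simulations because even at −70 mV the activation-curve tail
passes a few picoamperes, enough to bias gigaohm-level leak estimates.

### What is, and is not, identifiable

With noise-free synthetic data the full seven-parameter fit recovers the
generating values essentially exactly.  Under the generator's default 2 %
current noise, a Fisher-information reality sets in: $A$ and $B$ enter the
filtered currents almost solely through their ratio (the $O \leftrightarrow
C_3$ relaxation at ~18 µs is invisible behind a 2 kHz Bessel filter and is
barely excited by voltage steps, because $A$ and $B$ are voltage
independent), and $\beta$'s voltage dependence spans only ~17 % across
physiological tail voltages, so $n$ is weak as well.  Restarting the local
stage *at the true parameters* on noisy targets — the maximum-likelihood
floor — still scatters $n$, $A$ and $B$ by tens of percent, while
$\alpha_1$, $m$, $\beta_1$ and $N$ stay within a few percent.  The recovery
study (`analysis/05_parameter_recovery.R`) and the acceptance suite report
this honestly; it is a property of the experiment design, not of the
optimiser, and it explains why bound constraints matter for this model.

## Conductance–voltage analysis

Chord conductances are $G(V) = \bar I / (V - E_{rev})$ with $E_{rev} =
-73$ mV, excluding steps within 5 mV of reversal; Boltzmann fits
$G_{max}/(1 + e^{-(V - V_{50})/k})$ provide $V_{50}$, with a model-free
interpolation readout available (which of the two the study used for its
G–V figure is not stated).  Default windows follow the protocol structure:
late step for dark, final 1 ms of the light pulse for light conditions.
For the *shift* analysis the package evaluates the dark condition over the
same within-step window as the light condition: with the light pulse only
20 ms into the step, activation is still incomplete there, and comparing
against a late-step dark window would add a kinetic right-shift of several
millivolts that masks the stimulus effect.  With matched windows the
simulated $\Delta G_{50}$ is positive and strictly increasing over the
measured intensity series (1.6/7.5/13 mW mm⁻²); the printed magnitudes
(10/15/27 mV) depend on the study's cells and are not asserted numerically.
An optional linear leak correction (fitted to steps at or below −80 mV)
removes background and seal contributions.

## The synthetic cohort

`generate_cell()` draws the attached fraction from a Beta distribution
fitted to the measured quartiles (median 27.36 %, IQR 24.7–30.0 %;
Beta(35.38, 93.57) reproduces all three to < 6e−4) and the circuit
parameters from log-uniform ranges typical of HEK293 whole-cell work
($C_M$ 12–25 pF, $R_S$ 4–15 MΩ, $R_{seal}$ 2–10 GΩ, $R_B$ 0.5–2 GΩ,
$N$ 8000–20000).  `generate_sweeps()` adds white Gaussian noise to the
current at a configurable fraction (default 2 %) of each sweep's peak
unfiltered |I| before filtering, and stores the noise-free latent
trajectories beside every sweep.  The generator emulates capacitive
transients, Bessel filtering, per-cell channel-count variability and the
biphasic photostimulus; it does **not** emulate recording drift, seal
degradation, pipette capacitance, liquid-junction offsets, line
interference, or correlated (1/f) noise — so passing recovery tests show
that the estimators are correct and well-conditioned under the stated noise
model, not that real recordings of arbitrary quality would fit equally
well.  No neuron model is included: the source defines none, and
action-potential experiments are out of scope.

## Problem sizes

The shipped analyses and tests run at desk scale by choice: sweeps start
from the holding steady state so holds are shortened to 10–20 ms
(dynamically equivalent to the full 2.5 s hold), circuit simulations sample
at 25 kHz, estimation targets at 10 kHz with the integrator step tied to the
grid, and the swarm runs 40 particles for 60 iterations.  Study-scale
settings (full holds, swarm 200) are plain arguments.

## Known limitations

The amplifier is ideal in both modes (no compensation circuitry, no pipette
capacitance, no junction potentials).  The two-domain reduction is lumped —
no spatial cable structure within a domain.  The photostimulus is a
phenomenological waveform with explicit calibration constants, not an
electrochemical device model; absolute stimulus magnitudes in volts or
amperes are therefore conventions.  The wild-type inactivated state that the
source eliminated during optimisation is likewise absent here.
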