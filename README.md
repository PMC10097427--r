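# oepcsim

Biophysical modelling of **optoelectronic single-cell stimulation**: what
happens, electrically, when a cell sitting on an organic electrolytic
photocapacitor (OEPC) is hit by a millisecond light pulse while being
recorded in whole-cell patch clamp.

The package is aimed at electrophysiologists and modellers working with
photocapacitive / extracellular stimulation. It implements, end to end:

- a **sequential hidden-Markov gating model** of the Kv1.3 potassium channel
  (states `C0 ⇌ C1 ⇌ C2 ⇌ C3 ⇌ O`), with voltage-dependent closed-state
  rates `α(V) = α₁·exp(V/m)`, `β(V) = β₁·exp(−V/n)` and a voltage-independent
  opening pair `A`, `B`; macroscopic current `I = N·g·p_O·(V − E_K)`;
- the **whole-cell recording circuit** (`C_M`, access resistance `R_S`, seal
  `R_seal`, background leak `R_B`), with a causal 4th-order 2 kHz Bessel
  filter on the output current, in voltage clamp and current clamp (I = 0);
- the **two-domain stimulation model**: the membrane split into an attached
  domain facing the electrolyte cleft (potential `V_J`, seal `R_J` to bath)
  and a free domain facing the bath, each with its own gating, driven by a
  biphasic cathodic-leading photostimulus;
- the **equivalent-clamp-voltage inversion** `V_C′(t)`: the command waveform
  that would reproduce a measured current without any cleft stimulus;
- **G–V analysis** (chord conductances, Boltzmann fits, light-induced ΔG50
  shifts) and **parameter estimation** (hybrid particle-swarm + 
  Levenberg–Marquardt gating fit, per-cell channel count, patch-parameter
  refinement);
- a **synthetic-data generator** (cells, sweeps with noise and filtering,
  photostimulus waveforms) so the whole chain runs with no external data.

The fitted gating parameter set (`kv13_rates()`) is α₁ = 281.4283 s⁻¹,
m = 0.0255 V, β₁ = 120 s⁻¹, n = 0.5623 V, A = 4.4432×10⁴ s⁻¹,
B = 9.6566×10³ s⁻¹.

## Worked example

Simulate the activation protocol (hold −100 mV, 400 ms steps to +40 mV) for
a default cell, then stimulate the same cell at a sub-threshold hold:

```r
library(oepcsim)

pp <- patch_params()         # 20 pF, 8 MΩ access, 4 GΩ seal, 1 GΩ leak
ch <- channel_population()   # 12000 channels × 12 pS, E_K = −73 mV
rp <- kv13_rates()

prot <- sample_protocol(voltage_protocol(c(0.02, 0.4), c(-0.1, 0.04)),
                        NULL, fs = 25000)
sw <- simulate_voltage_clamp(prot, pp, ch, rp)
mean(sw$i_out[sw$t > 0.40]) * 1e9        # steady outward current at +40 mV
#> 6.18  (nA; open probability 0.670, whole-cell conductance 96.5 nS)

# OEPC light pulse (13 mW/mm², 5 ms) at a −50 mV hold
td <- simulate_two_domain("vc",
        sample_protocol(voltage_protocol(c(0.02, 0.08), c(-0.05, -0.05)),
                        light_protocol(0.04, 0.005, 13), 25000),
        pp, two_domain_geometry(), cleft_params(), ch, rp,
        stimulus = photostimulus(13, onset = 0.04, duration = 0.005))
```

The attached membrane (27.36 % of the cell by default) depolarises by
**+32 mV** during the pulse and undershoots by −59 mV at light-off, while the
free membrane barely moves; the attached-domain Kv1.3 conductance rises by
≈1.1 nS even though the channels would not conduct at −50 mV without light.
Inverting the simulated current with `equivalent_clamp_voltage()` yields a
biphasic command waveform: positive leading phase (+10.4 mV), sustained
plateau (+9.8 mV), negative off-transient (−14.0 mV).

The `analysis/` scripts run the full workflow and write their tables under
`results/`: `01` channel kinetics, `02` whole-cell activation sweeps, `03`
OEPC stimulation + equivalent voltage, `04` the ΔG50 intensity series
(+1.4 / +4.2 / +5.4 mV at 1.6 / 7.5 / 13 mW/mm² — positive and strictly
ordered), `05` the parameter-recovery study (exact recovery noise-free;
α₁, m, β₁, N within a few percent at 2 % noise, with n, A, B weakly
identified — see the methods vignette for the identifiability analysis).

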