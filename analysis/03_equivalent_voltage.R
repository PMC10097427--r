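#!/usr/bin/env Rscript
# OEPC stimulation in voltage clamp at a sub-threshold hold (-50 mV), the
# equivalent-clamp-voltage inversion, and the light-induced conductance
# increase of the attached membrane.
#
# Writes: results/oepc_vc_trace.csv, results/equivalent_voltage.csv

suppressPackageStartupMessages(library(oepcsim))
dir.create("results", showWarnings = FALSE)

pp <- patch_params(); ch <- channel_population(); rp <- kv13_rates()
geom <- two_domain_geometry()     # attached fraction 27.36 %
cl <- cleft_params()              # R_J = 10 MOhm, C_E ~ 5.5 pF
fs <- 25000

vp <- voltage_protocol(c(0.02, 0.08), c(-0.05, -0.05))
lp <- light_protocol(0.04, 0.005, 13)
prot <- sample_protocol(vp, lp, fs)
stim <- photostimulus(13, onset = 0.04, duration = 0.005)

td <- simulate_two_domain("vc", prot, pp, geom, cl, ch, rp, stimulus = stim,
                          filter = NULL)
st <- td$state
write.csv(data.frame(t_s = st$t, V_M_attached_mV = st$V_M_attached * 1e3,
                     V_M_free_mV = st$V_M_free * 1e3,
                     G_attached_nS = st$G_attached * 1e9,
                     I_out_pA = attr(td$sweep, "i_raw") * 1e12),
          "results/oepc_vc_trace.csv", row.names = FALSE)

pulse <- st$t >= 0.04 & st$t < 0.045
base_att <- mean(st$V_M_attached[st$t < 0.04])
cat(sprintf("Attached membrane at -50 mV hold: depolarizes by %.1f mV during the pulse,\n",
            (max(st$V_M_attached[pulse]) - base_att) * 1e3))
cat(sprintf("undershoots by %.1f mV at light-off.\n",
            (min(st$V_M_attached[st$t >= 0.045 & st$t < 0.055]) - base_att) * 1e3))
dG <- conductance_increase(st)
cat(sprintf("Peak attached-membrane conductance increase: %.2f nS\n",
            max(dG$delta_G[pulse]) * 1e9))

# invert the simulated OEPC current into the equivalent clamp voltage
inv <- equivalent_clamp_voltage(attr(td$sweep, "i_raw"), st$t, pp, ch, rp)
write.csv(data.frame(t_s = inv$t, V_C_prime_mV = inv$v_c_prime * 1e3),
          "results/equivalent_voltage.csv", row.names = FALSE)
dv <- (inv$v_c_prime + 0.05) * 1e3
cat(sprintf("Equivalent clamp voltage V_C': peak %+.1f mV, plateau %+.1f mV, off-minimum %+.1f mV\n",
            max(dv[pulse]), mean(dv[st$t >= 0.0435 & st$t < 0.0449]),
            min(dv[st$t >= 0.045 & st$t < 0.055])))
cat("(biphasic, cathodic-leading: positive phase, sustained plateau, negative off-transient)\n")
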