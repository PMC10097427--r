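#!/usr/bin/env Rscript
# Kv1.3 gating model: rate laws, steady-state activation and relaxation
# kinetics of the fitted parameter set.
#
# Writes: results/rate_laws.csv, results/steady_state_activation.csv

suppressPackageStartupMessages(library(oepcsim))
dir.create("results", showWarnings = FALSE)

rp <- kv13_rates()
cat("Fitted TagRFP-Kv1.3 gating parameters:\n")
cat(sprintf("  alpha(V) = %.4f * exp(V / %.4f V)  s^-1\n", rp$alpha1, rp$m))
cat(sprintf("  beta(V)  = %.1f * exp(-V / %.4f V)  s^-1\n", rp$beta1, rp$n))
cat(sprintf("  C3->O: A = %.1f s^-1,  O->C3: B = %.1f s^-1 (voltage independent)\n",
            rp$A, rp$B))

V <- seq(-0.100, 0.060, by = 0.002)
rates_tab <- data.frame(V_mV = V * 1e3,
                        alpha_per_s = forward_rate(V, rp),
                        beta_per_s = backward_rate(V, rp))
write.csv(rates_tab, "results/rate_laws.csv", row.names = FALSE)

ss <- t(vapply(V, function(v) steady_state(v, rp), numeric(5)))
act <- data.frame(V_mV = V * 1e3, p_open = ss[, "O"])
write.csv(cbind(act, ss[, 1:4]), "results/steady_state_activation.csv",
          row.names = FALSE)

# half-activation of the steady-state open probability
pmax_ <- max(act$p_open)
v50 <- approx(act$p_open, act$V_mV, xout = pmax_ / 2)$y
cat(sprintf("\nSteady-state open probability saturates at %.3f (limit A/(A+B) = %.3f)\n",
            pmax_, rp$A / (rp$A + rp$B)))
cat(sprintf("Half-activation of the steady-state curve: %.1f mV\n", v50))

# activation time course at two step potentials
for (vstep in c(0, 0.04)) {
  t <- seq(0, 0.05, by = 1e-4)
  P <- propagate(steady_state(-0.1, rp), t, rep(vstep, length(t)), rp,
                 method = "matrix_exponential")
  t90 <- t[which(P[, "O"] >= 0.9 * P[nrow(P), "O"])[1]]
  cat(sprintf("Step -100 -> %+.0f mV: p_O reaches 90%% of its plateau in %.1f ms\n",
              vstep * 1e3, t90 * 1e3))
}
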