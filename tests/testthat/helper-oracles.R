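# Independent oracles used across the suite.  These deliberately avoid the
# package's own solution paths: closed forms, detailed balance, and direct
# arithmetic.

# detailed-balance steady state of the sequential chain:
# p[i+1]/p[i] = alpha/beta on closed steps, p[O]/p[C3] = A/B
db_steady_state <- function(V, rp) {
  a <- rp$alpha1 * exp(V / rp$m)
  b <- rp$beta1 * exp(-V / rp$n)
  w <- cumprod(c(1, rep(a / b, rp$n_closed - 1L), rp$A / rp$B))
  w / sum(w)
}

db_open_prob <- function(V, rp) {
  p <- db_steady_state(V, rp)
  p[length(p)]
}

# closed-form output current of the passive R_S / (R_B || C_M) network with
# an R_seal shunt, for a command step from vc1 to vc2 at t = t0
# (E_VHEK = 0).  Membrane voltage relaxes exponentially between the two
# voltage-divider equilibria.
rc_step_current <- function(t, t0, vc1, vc2, patch) {
  RS <- patch$R_S; RB <- patch$R_B; CM <- patch$C_M; Rseal <- patch$R_seal
  V1 <- vc1 * RB / (RB + RS)
  V2 <- vc2 * RB / (RB + RS)
  tau <- CM * RS * RB / (RS + RB)
  V <- ifelse(t < t0, V1, V2 + (V1 - V2) * exp(-(t - t0) / tau))
  vc <- ifelse(t < t0, vc1, vc2)
  (vc - V) / RS + vc / Rseal
}

trapz <- function(y, dt) dt * (sum(y) - (y[1] + y[length(y)]) / 2)

# small standard fixtures
quick_patch <- function(...) patch_params(C_M = 20e-12, R_S = 8e6,
                                          R_seal = 4e9, R_B = 1e9, ...)

quick_cell <- function(N = 12000) {
  list(patch = quick_patch(), channels = channel_population(N = N),
       geom = two_domain_geometry(), seed = 0L)
}

# short activation + deactivation family used by the estimation tests
fit_family <- function() {
  act <- step_family(-0.1, 0.01, 0.1, -0.04, 0.04, 0.04)
  tails <- lapply(c(-0.12, -0.08, -0.06), function(v) {
    p <- voltage_protocol(c(0.01, 0.03, 0.06), c(-0.1, 0.04, v))
    p$step_level <- v
    p
  })
  c(act, tails)
}

eq7_truth <- c(alpha1 = 281.4283, m = 0.0255, beta1 = 120, n = 0.5623,
               A = 4.4432e4, B = 9.6566e3, N = 12000)
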