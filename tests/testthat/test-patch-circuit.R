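test_that("the discrete Bessel filter is unity-DC, causal, stable and low-pass", {
  fs <- 50000
  spec <- filter_spec()
  y <- apply_filter(rep(1, 2000), fs, spec)
  expect_lt(abs(tail(y, 1) - 1), 1e-3)

  # causal: no output before the impulse
  x <- c(rep(0, 100), 1, rep(0, 899))
  h <- apply_filter(x, fs, spec)
  expect_identical(h[1:100], rep(0, 100))
  # stable: impulse response decays, discrete poles inside the unit circle
  expect_lt(max(abs(tail(h, 100))), 1e-6 * max(abs(h)))
  ba <- oepcsim:::bessel_digital(spec, fs)
  expect_true(all(Mod(polyroot(rev(ba$a))) < 1))

  # low-pass: white noise loses variance
  set.seed(1)
  w <- rnorm(5000)
  expect_lt(var(apply_filter(w, fs, spec)), var(w))

  expect_error(apply_filter(rep(1, 10), 3000, spec), "twice the filter cutoff")
})

test_that("discrete impulse response matches the continuous filter solved by ODE", {
  fs <- 50000
  spec <- filter_spec()
  n <- 600
  h_disc <- apply_filter(c(1, rep(0, n - 1)), fs, spec)

  # continuous-time oracle: companion-form state space integrated by lsoda
  proto <- oepcsim:::bessel_analog(spec$order, spec$cutoff)
  a_poly <- Re(oepcsim:::polymul(oepcsim:::polymul(c(1, -proto$poles[1]),
                                                  c(1, -proto$poles[2])),
                                 oepcsim:::polymul(c(1, -proto$poles[3]),
                                                   c(1, -proto$poles[4]))))
  A <- matrix(0, 4, 4)
  A[1, ] <- -a_poly[-1]
  A[cbind(2:4, 1:3)] <- 1
  rhs <- function(t, y, parms) list(as.vector(A %*% y))
  y0 <- c(proto$gain, 0, 0, 0)   # impulse loads the first state
  tt <- (seq_len(n) - 1) / fs
  sol <- deSolve::lsoda(y0, tt, rhs, parms = NULL, rtol = 1e-10, atol = 1e-14)
  h_cont <- sol[, 5] / fs        # output = last companion state, per sample
  rel_rms <- sqrt(mean((h_disc - h_cont)^2) / mean(h_cont^2))
  expect_lt(rel_rms, 0.01)
})

test_that("with channels disabled the clamp responds like the analytic RC network", {
  pp <- quick_patch(E_VHEK = 0)
  fs <- 50000
  t <- seq(0, 0.02 - 1 / fs, by = 1 / fs)
  prot <- data.frame(t = t, v_cmd = ifelse(t < 0.005, 0, 0.05))
  sw <- simulate_voltage_clamp(prot, pp, filter = NULL)
  i_raw <- attr(sw, "i_raw")
  i_th <- rc_step_current(t, 0.005, 0, 0.05, pp)
  expect_lt(max(abs(i_raw - i_th)) / max(abs(i_th)), 1e-4)
})

test_that("a quiescent clamp with all reversals at zero produces no current", {
  pp <- quick_patch(E_VHEK = 0)
  ch <- channel_population(E_K = 0)
  t <- seq(0, 0.01, by = 2e-5)
  prot <- data.frame(t = t, v_cmd = rep(0, length(t)))
  sw <- simulate_voltage_clamp(prot, pp, ch, kv13_rates(), filter = NULL)
  expect_lt(max(abs(attr(sw, "i_raw"))), 1e-18)
})

test_that("the passive circuit is linear: superposition of command waveforms", {
  pp <- quick_patch(E_VHEK = 0)
  fs <- 25000
  t <- seq(0, 0.02 - 1 / fs, by = 1 / fs)
  u1 <- ifelse(t < 0.01, 0, 0.03)
  u2 <- 0.02 * sin(2 * pi * 50 * t)
  out <- function(u) attr(simulate_voltage_clamp(
    data.frame(t = t, v_cmd = u), pp, filter = NULL, V0 = 0), "i_raw")
  i12 <- out(u1 + u2)
  expect_lt(max(abs(i12 - (out(u1) + out(u2)))) / max(abs(i12)), 1e-8)
})

test_that("capacitive transient charge matches the closed form", {
  fs <- 100000
  t <- seq(0, 0.05 - 1 / fs, by = 1 / fs)
  dV <- 0.04
  mk <- function(pp) {
    prot <- data.frame(t = t, v_cmd = ifelse(t < 0.005, 0, dV))
    attr(simulate_voltage_clamp(prot, pp, filter = NULL), "i_raw")
  }
  # no background, no seal: all charge lands on C_M
  pp0 <- patch_params(C_M = 20e-12, R_S = 8e6, R_seal = 1e15, R_B = 1e15,
                      E_VHEK = 0)
  q <- trapz(mk(pp0)[t >= 0.005], 1 / fs)
  expect_lt(abs(q / (20e-12 * dV) - 1), 1e-3)
  # finite R_B: transient charge above steady state carries the divider squared
  pp1 <- patch_params(C_M = 20e-12, R_S = 8e6, R_seal = 1e15, R_B = 0.5e9,
                      E_VHEK = 0)
  i <- mk(pp1)[t >= 0.005]
  iss <- dV / (0.5e9 + 8e6)
  q1 <- trapz(i - iss, 1 / fs)
  expect_lt(abs(q1 / (20e-12 * dV * (0.5e9 / (0.5e9 + 8e6))^2) - 1), 1e-3)
})

test_that("activation currents rise with sigmoidal delay to a plateau within 50 ms", {
  pp <- quick_patch()
  fs <- 25000
  t <- seq(0, 0.2 - 1 / fs, by = 1 / fs)
  prot <- data.frame(t = t, v_cmd = ifelse(t < 0.01, -0.1, 0.04))
  sw <- simulate_voltage_clamp(prot, pp, channel_population(), kv13_rates())
  i <- sw$i_out
  plateau <- mean(i[t > 0.19])
  expect_gt(plateau, 1e-9)                     # strong outward current
  i60 <- mean(i[t > 0.058 & t < 0.062])        # 50 ms into the step
  expect_lt(abs(i60 - plateau) / plateau, 0.02)
  # delayed sigmoid: current soon after the (settled) capacitive transient
  # is still a small fraction of the plateau
  i2 <- mean(i[t > 0.0115 & t < 0.012])
  expect_lt(i2 / plateau, 0.5)
  expect_gt(which.max(diff(i[t > 0.011])), 3)  # inflection after onset
})

test_that("the fixed-step scheme tracks the adaptive-ODE reference", {
  pp <- quick_patch()
  fs <- 25000
  t <- seq(0, 0.1 - 1 / fs, by = 1 / fs)
  prot <- data.frame(t = t, v_cmd = ifelse(t < 0.01, -0.1, 0.02))
  sw <- simulate_voltage_clamp(prot, pp, channel_population(), kv13_rates(),
                               filter = NULL)
  ode <- simulate_voltage_clamp_ode(prot, pp, channel_population(),
                                    kv13_rates(), rtol = 1e-10, atol = 1e-14)
  expect_lt(max(abs(ode$V - attr(sw, "v_m"))), 2e-5)           # < 0.02 mV
  expect_lt(max(abs(ode$I_out - attr(sw, "i_raw"))) /
              max(abs(ode$I_out)), 2e-4)
})

test_that("current clamp: leak equilibrium, RC charging, channel loading", {
  pp <- quick_patch(E_VHEK = -0.060)
  t <- seq(0, 0.5, by = 1e-4)
  # I = 0: settles exactly to the background reversal
  sw <- simulate_current_clamp(t, 0, pp, V0 = -0.02)
  expect_equal(tail(attr(sw, "v_m"), 1), -0.060, tolerance = 1e-9)
  # constant injection: V -> E + I R_B along exp(-t / (R_B C_M))
  I0 <- 1e-11
  sw2 <- simulate_current_clamp(t, I0, pp, V0 = -0.060)
  tau <- pp$R_B * pp$C_M
  v_th <- -0.060 + I0 * pp$R_B * (1 - exp(-t / tau))
  expect_lt(max(abs(attr(sw2, "v_m") - v_th)), 1e-9)
  # an added outward conductance keeps the steady voltage below passive
  sw3 <- simulate_current_clamp(t, I0, pp, channel_population(),
                                kv13_rates(), V0 = -0.060)
  expect_lt(tail(attr(sw3, "v_m"), 1), tail(attr(sw2, "v_m"), 1))
})
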