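test_that("rate laws reduce to their prefactors at 0 mV and scale as exp", {
  rp <- rate_params(alpha1 = 123.4, m = 0.03, beta1 = 45.6, n = 0.4,
                    A = 1e4, B = 5e3)
  expect_identical(forward_rate(0, rp), 123.4)
  expect_identical(backward_rate(0, rp), 45.6)

  # one slope voltage of depolarisation multiplies the rate by e exactly
  eq7 <- kv13_rates()
  expect_equal(forward_rate(0.0255, eq7), eq7$alpha1 * exp(1),
               tolerance = 1e-14)
  expect_equal(backward_rate(-0.5623, eq7), eq7$beta1 * exp(1),
               tolerance = 1e-14)

  # monotonicity
  V <- seq(-0.2, 0.2, by = 0.01)
  expect_true(all(diff(forward_rate(V, eq7)) > 0))
  expect_true(all(diff(backward_rate(V, eq7)) < 0))

  # overflow guard
  expect_error(forward_rate(30, eq7), "overflow")
  expect_error(rate_params(-1, 0.03, 45, 0.4, 1e4, 5e3), "> 0")
})

test_that("the generator matrix encodes the sequential chain", {
  rp <- kv13_rates()
  for (V in c(-0.1, -0.016, 0.04)) {
    Q <- rate_matrix(V, rp)
    expect_lt(max(abs(rowSums(Q))), 1e-8)   # absolute, rates up to ~1e5 s^-1
    off <- Q; diag(off) <- 0
    expect_true(all(off >= 0))
    expect_identical(Q["C0", "C1"], forward_rate(V, rp))
    expect_identical(Q["C2", "C1"], backward_rate(V, rp))
  }
  # the open-transition pair is voltage independent
  Q1 <- rate_matrix(-0.08, rp); Q2 <- rate_matrix(0.03, rp)
  expect_identical(Q1["C3", "O"], Q2["C3", "O"])
  expect_identical(Q1["O", "C3"], Q2["O", "C3"])
  expect_identical(Q1["C3", "O"], rp$A)
  expect_identical(Q1["O", "C3"], rp$B)
})

test_that("null-space steady state matches detailed balance and the ODE limit", {
  rp <- kv13_rates()
  for (V in c(-0.1, -0.05, -0.016, 0, 0.04)) {
    ss <- steady_state(V, rp)
    expect_lt(max(abs(ss - db_steady_state(V, rp))), 1e-10)
    # 10 s at constant voltage reaches the same distribution
    P <- propagate(rep(c(0.25, 0), c(4, 1)), c(0, 10), rep(V, 2), rp,
                   method = "matrix_exponential")
    expect_lt(max(abs(P[2, ] - ss)), 1e-8)
  }
  # deep hyperpolarisation parks every channel in C0
  ss <- steady_state(-0.5, rp)
  expect_gt(ss["C0"], 1 - 1e-6)
  expect_lt(ss["O"], 1e-9)
})

test_that("steady-state open probability is monotone and saturates at A/(A+B)", {
  rp <- kv13_rates()
  V <- seq(-0.1, 0.06, by = 0.005)
  pO <- vapply(V, function(v) steady_state(v, rp)[["O"]], numeric(1))
  expect_true(all(diff(pO) >= 0))
  expect_lt(abs(steady_state(1, rp)[["O"]] - rp$A / (rp$A + rp$B)), 1e-3)
})

test_that("the propagator conserves probability and both methods agree", {
  rp <- kv13_rates()
  t <- seq(0, 0.05, by = 2e-5)
  V <- ifelse(t < 0.005, -0.1, 0)
  p0 <- steady_state(-0.1, rp)
  P1 <- propagate(p0, t, V, rp, method = "matrix_exponential")
  P2 <- propagate(p0, t, V, rp, method = "adaptive_ode")
  expect_lt(max(abs(rowSums(P1) - 1)), 1e-9)
  expect_lt(max(abs(P1[, "O"] - P2[, "O"])), 1e-6)

  # a steady state is a fixed point
  pss <- steady_state(-0.02, rp)
  Pc <- propagate(pss, t, rep(-0.02, length(t)), rp,
                  method = "matrix_exponential")
  expect_lt(max(abs(sweep(Pc, 2, pss))), 1e-12)

  # the exact propagator refuses non-piecewise-constant input
  expect_error(propagate(p0, t, function(tt) -0.1 + tt, rp,
                         method = "matrix_exponential"),
               "piecewise-constant")
  expect_error(propagate(c(0.6, 0.6, 0, 0, 0), t, V, rp), "sum to 1")
})

test_that("channel current follows I = N g pO (V - E_K)", {
  pop <- channel_population(N = 1000, g = 12e-12, E_K = -0.073)
  expect_identical(channel_current(0.4, -0.073, pop), 0)
  expect_identical(channel_current(0, 0.04, pop), 0)
  # direct arithmetic oracle
  expect_equal(channel_current(0.5, 0, pop), 1000 * 12e-12 * 0.5 * 0.073,
               tolerance = 1e-15)
  expect_equal(channel_conductance(0.5, pop), 6e-9, tolerance = 1e-15)
})

test_that("alternative chain lengths are supported outside the compiled path", {
  rp5 <- rate_params(281.4283, 0.0255, 120, 0.5623, 4.4432e4, 9.6566e3,
                     n_closed = 5L)
  Q <- rate_matrix(0, rp5)
  expect_equal(dim(Q), c(6, 6))
  expect_equal(unname(rowSums(Q)), rep(0, 6), tolerance = 1e-12)
  ss <- steady_state(0, rp5)
  expect_lt(max(abs(ss - db_steady_state(0, rp5))), 1e-10)
  t <- c(0, 0.01, 5)
  P <- propagate(c(1, 0, 0, 0, 0, 0), t, rep(0, 3), rp5,
                 method = "matrix_exponential")
  expect_lt(max(abs(P[3, ] - ss)), 1e-7)
})
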