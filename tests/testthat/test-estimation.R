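test_that("the bound box contains the default parameter set and validates", {
  b <- fit_bounds()
  expect_true(all(b$lower < b$upper))
  rp <- kv13_rates()
  v <- c(rp$alpha1, rp$m, rp$beta1, rp$n, rp$A, rp$B)
  expect_true(all(v > b$lower[1:6] & v < b$upper[1:6]))
  expect_error(fit_bounds(lower = c(alpha1 = 300, m = 0.01, beta1 = 90,
                                    n = 0.1, A = 2000, B = 1500, N = 8000)),
               "inside the bound box")
  expect_error(fit_bounds(upper = c(alpha1 = 50, m = 0.5, beta1 = 200, n = 1,
                                    A = 5e4, B = 2e4, N = 2e4)), "lower bounds")
})

test_that("the particle swarm is seeded-deterministic with monotone best-so-far", {
  sphere <- function(x) sum((x - c(1, 2, 3))^2)
  s1 <- oepcsim:::pso_minimize(sphere, rep(-5, 3), rep(5, 3), 20, 50, seed = 7)
  s2 <- oepcsim:::pso_minimize(sphere, rep(-5, 3), rep(5, 3), 20, 50, seed = 7)
  expect_identical(s1, s2)
  expect_true(all(diff(s1$history) <= 0))
  expect_lt(max(abs(s1$par - c(1, 2, 3))), 0.05)
  # non-finite objectives are rejected, not propagated
  spiky <- function(x) if (x[1] > 0) NaN else sum(x^2)
  s3 <- oepcsim:::pso_minimize(spiky, -2, 2, 10, 20, seed = 1)
  expect_true(is.finite(s3$value))
})

test_that("the current-residual objective vanishes at the generating parameters", {
  cell <- quick_cell()
  tg <- generate_sweeps(cell, fit_family(), noise_rms = 0, fs = 10000,
                        seed = 1, h_max = 1e-4)
  fn <- oepcsim:::gating_objective_factory(tg, cell$patch, 12e-12, -0.073,
                                           filter_spec(), h_max = 1e-4)
  expect_identical(fn(unname(eq7_truth)), 0)
  expect_gt(fn(unname(eq7_truth) * 1.05), 0)
})

test_that("per-cell channel count is recovered and scales with the currents", {
  cell <- quick_cell()
  rp <- kv13_rates()
  fam <- step_family(-0.1, 0.01, 0.4, -0.02, 0.04, 0.02)
  tg <- generate_sweeps(cell, fam, noise_rms = 0, fs = 10000, seed = 1)
  Nhat <- fit_channel_count(tg, cell$patch, rp)
  expect_lt(abs(Nhat - 12000) / 12000, 1e-3)
  # linearity in N: with a negligible series-resistance drop, doubling every
  # measured current doubles the recovered count
  cell2 <- quick_cell()
  cell2$patch <- patch_params(C_M = 20e-12, R_S = 1e3, R_seal = 1e14,
                              R_B = 1e14)
  tg2 <- generate_sweeps(cell2, fam, noise_rms = 0, fs = 10000, seed = 1)
  N1 <- fit_channel_count(tg2, cell2$patch, rp)
  tg2x <- lapply(tg2, function(s) { s$i_out <- 2 * s$i_out; s })
  N2 <- fit_channel_count(tg2x, cell2$patch, rp)
  expect_equal(N2 / N1, 2, tolerance = 1e-3)

  expect_error(fit_channel_count(tg, cell$patch, rp, interval = c(5, 2)),
               "interval")
  expect_error(fit_channel_count(tg, cell$patch, rp, current_floor = 1),
               "floor")
})

test_that("patch parameters are recovered from perturbed starts", {
  cell <- quick_cell()
  rp <- kv13_rates()
  fam <- step_family(-0.1, 0.01, 0.1, -0.1, -0.07, 0.01)
  tg <- generate_sweeps(cell, fam, noise_rms = 0, fs = 25000, seed = 2)
  truth <- c(C_M = 20e-12, R_S = 8e6, R_seal = 4e9, R_B = 1e9)
  # starting at the truth stays put
  fp0 <- fit_patch_parameters(tg, cell$patch, channels = cell$channels,
                              rates = rp)
  est0 <- c(fp0$C_M, fp0$R_S, fp0$R_seal, fp0$R_B)
  expect_lt(max(abs(est0 - truth) / truth), 1e-3)
  # +-20 % perturbed start recovers within 2 %
  start <- patch_params(C_M = 24e-12, R_S = 6.4e6, R_seal = 4.8e9,
                        R_B = 0.8e9)
  fp <- fit_patch_parameters(tg, start, channels = cell$channels, rates = rp)
  est <- c(fp$C_M, fp$R_S, fp$R_seal, fp$R_B)
  expect_lt(max(abs(est - truth) / truth), 0.02)
  expect_error(fit_patch_parameters(tg[4], start), "two sub-threshold")
})

test_that("membrane capacitance is identified through the transient charge", {
  rp <- kv13_rates()
  fam <- step_family(-0.1, 0.01, 0.1, -0.1, -0.07, 0.01)
  start <- patch_params(C_M = 17e-12, R_S = 9e6, R_seal = 5e9, R_B = 1.2e9)
  fitted_cm <- vapply(c(20e-12, 10e-12), function(cm) {
    cell <- quick_cell()
    cell$patch <- patch_params(C_M = cm, R_S = 8e6, R_seal = 4e9, R_B = 1e9)
    tg <- generate_sweeps(cell, fam, noise_rms = 0, fs = 25000, seed = 2)
    fit_patch_parameters(tg, start, channels = cell$channels, rates = rp)$C_M
  }, numeric(1))
  expect_equal(fitted_cm[2] / fitted_cm[1], 0.5, tolerance = 1e-3)
})

test_that("a reduced swarm fit reproduces itself under the same seed", {
  cell <- quick_cell()
  tg <- generate_sweeps(cell, fit_family()[c(3, 5)], noise_rms = 0.02,
                        fs = 10000, seed = 4, h_max = 1e-4)
  f1 <- fit_gating_parameters(tg, cell$patch, swarm_size = 6, n_iter = 3,
                              seed = 9, n_polish = 0, h_max = 1e-4)
  f2 <- fit_gating_parameters(tg, cell$patch, swarm_size = 6, n_iter = 3,
                              seed = 9, n_polish = 0, h_max = 1e-4)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$objective, f2$objective)
  expect_true(all(diff(f1$history) <= 0))
  expect_true(all(f1$par >= fit_bounds()$lower & f1$par <= fit_bounds()$upper))
})
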