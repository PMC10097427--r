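#' Parameter bounds for gating-parameter estimation
#'
#' Box bounds over the ordered parameter set
#' `[alpha1, m, beta1, n, A, B, N]` (s^-1, V, s^-1, V, s^-1, s^-1, count).
#' The default box is a reconstruction of the published Kv1.3 bounds —
#' the printed vectors are garbled in the source — chosen so that the fitted
#' parameter set lies strictly inside it; this containment is enforced at
#' construction.  Fully user-overridable.
#'
#' @param lower,upper named numeric vectors over
#'   `alpha1, m, beta1, n, A, B, N`
#' @return object of class `fit_bounds`
#' @export
fit_bounds <- function(lower = c(alpha1 = 100, m = 0.01, beta1 = 90, n = 0.1,
                                 A = 2000, B = 1500, N = 8000),
                       upper = c(alpha1 = 500, m = 0.5, beta1 = 200, n = 1,
                                 A = 50000, B = 20000, N = 20000)) {
  nm <- c("alpha1", "m", "beta1", "n", "A", "B", "N")
  stopifnot(all(nm %in% names(lower)), all(nm %in% names(upper)))
  lower <- lower[nm]; upper <- upper[nm]
  if (any(lower >= upper)) stop("lower bounds must be < upper bounds elementwise")
  ref <- kv13_rates()
  ref_vec <- c(alpha1 = ref$alpha1, m = ref$m, beta1 = ref$beta1, n = ref$n,
               A = ref$A, B = ref$B, N = 12000)
  if (any(ref_vec[1:6] < lower[1:6]) || any(ref_vec[1:6] > upper[1:6]))
    stop("default gating parameter set must lie inside the bound box")
  structure(list(lower = lower, upper = upper), class = "fit_bounds")
}

# Constriction-coefficient particle swarm (Clerc-Kennedy chi = 0.7298,
# c1 = c2 = 1.49618), box-constrained by reflection, deterministic given the
# seed.  Best-so-far objective is monotone non-increasing by construction.
pso_minimize <- function(fn, lower, upper, swarm_size, n_iter, seed,
                         trace = FALSE) {
  d <- length(lower)
  with_seed(seed, {
    chi <- 0.7298; c1 <- 1.49618; c2 <- 1.49618
    span <- upper - lower
    X <- matrix(runif(swarm_size * d), swarm_size, d)
    X <- sweep(sweep(X, 2, span, "*"), 2, lower, "+")
    V <- matrix(runif(swarm_size * d, -1, 1), swarm_size, d) *
      matrix(span, swarm_size, d, byrow = TRUE) * 0.1
    f <- apply(X, 1, fn)
    f[!is.finite(f)] <- Inf  # non-finite candidates rejected
    Pb <- X; fPb <- f
    g <- which.min(fPb)
    hist <- numeric(n_iter)
    for (it in seq_len(n_iter)) {
      R1 <- matrix(runif(swarm_size * d), swarm_size, d)
      R2 <- matrix(runif(swarm_size * d), swarm_size, d)
      Gb <- matrix(Pb[g, ], swarm_size, d, byrow = TRUE)
      V <- chi * (V + c1 * R1 * (Pb - X) + c2 * R2 * (Gb - X))
      X <- X + V
      # reflect at the box and damp the velocity component
      for (j in seq_len(d)) {
        lo <- X[, j] < lower[j]; hi <- X[, j] > upper[j]
        X[lo, j] <- 2 * lower[j] - X[lo, j]
        X[hi, j] <- 2 * upper[j] - X[hi, j]
        X[, j] <- pmin(pmax(X[, j], lower[j]), upper[j])
        V[lo | hi, j] <- -0.5 * V[lo | hi, j]
      }
      f <- apply(X, 1, fn)
      f[!is.finite(f)] <- Inf
      imp <- f < fPb
      Pb[imp, ] <- X[imp, ]
      fPb[imp] <- f[imp]
      g <- which.min(fPb)
      hist[it] <- fPb[g]
      if (trace && it %% 10 == 0)
        message("pso iter ", it, ": best objective ", signif(fPb[g], 6))
    }
    ord <- order(fPb)
    list(par = Pb[g, ], value = fPb[g], swarm_best = Pb[ord, , drop = FALSE],
         swarm_value = fPb[ord], history = hist)
  })
}

# simulate the sweep family for one parameter vector and return the summed
# squared current residual against the targets
gating_objective_factory <- function(sweeps, patch, g_single, E_K, filter,
                                     h_max = 2e-5) {
  protos <- lapply(sweeps, function(s) s[, c("t", "v_cmd")])
  targets <- lapply(sweeps, function(s) s$i_out)
  function(par) {
    rp <- tryCatch(rate_params(par[1], par[2], par[3], par[4], par[5], par[6]),
                   error = function(e) NULL)
    if (is.null(rp)) return(Inf)
    pop <- channel_population(N = par[7], g = g_single, E_K = E_K)
    sse <- 0
    for (i in seq_along(protos)) {
      sim <- tryCatch(
        simulate_voltage_clamp(protos[[i]], patch, pop, rp, filter = filter,
                               h_max = h_max),
        error = function(e) NULL)
      if (is.null(sim)) return(Inf)
      sse <- sse + sum((sim$i_out - targets[[i]])^2)
    }
    sse
  }
}

# stacked scaled residual vector over all sweeps, in log-parameter space
gating_residual_factory <- function(sweeps, patch, g_single, E_K, filter,
                                    h_max = 2e-5) {
  protos <- lapply(sweeps, function(s) s[, c("t", "v_cmd")])
  targets <- unlist(lapply(sweeps, function(s) s$i_out))
  scl <- max(abs(targets))
  function(z) {
    par <- exp(z)
    rp <- rate_params(par[1], par[2], par[3], par[4], par[5], par[6])
    pop <- channel_population(N = par[7], g = g_single, E_K = E_K)
    sim <- unlist(lapply(protos, function(pr)
      simulate_voltage_clamp(pr, patch, pop, rp, filter = filter,
                             h_max = h_max)$i_out))
    (sim - targets) / scl
  }
}

#' Fit gating parameters by hybrid particle-swarm optimisation
#'
#' Global swarm search over the bound box followed by local refinement:
#' Levenberg-Marquardt on the stacked current-residual vector in
#' log-parameter space (started from the best particles), minimising the
#' summed squared residual between simulated and target output currents over
#' all sweeps.  Deterministic given the seed.
#'
#' @param sweeps voltage-clamp sweep family (targets), simulated or recorded
#'   under known protocols; each sweep provides `t`, `v_cmd`, `i_out`
#' @param patch known [patch_params()] of the cell
#' @param bounds a [fit_bounds()]
#' @param swarm_size number of particles (study scale 200; scaled-down runs
#'   use 40)
#' @param n_iter swarm iterations
#' @param seed integer seed
#' @param g_single single-channel conductance (S) held fixed; `N` absorbs it
#' @param E_K reversal potential (V)
#' @param filter [filter_spec()] applied to candidate simulations (match the
#'   targets' filtering), or NULL
#' @param n_polish number of best particles refined locally
#' @param polish_maxit Levenberg-Marquardt iteration cap per start
#' @param h_max maximum integrator substep (s); match the value used to
#'   produce the targets so that discretisation bias cancels
#' @return object of class `fit_result`: `parameters` ([rate_params()]),
#'   `N`, `objective`, `par` (named vector), plus convergence diagnostics
#'   (`history`, `swarm_size`, `n_iter`, `seed`) and `residuals` per sweep
#' @export
fit_gating_parameters <- function(sweeps, patch, bounds = fit_bounds(),
                                  swarm_size = 40, n_iter = 60, seed = 1,
                                  g_single = 12e-12, E_K = -0.073,
                                  filter = filter_spec(), n_polish = 2,
                                  polish_maxit = 100, h_max = 2e-5) {
  stopifnot(inherits(bounds, "fit_bounds"))
  fn <- gating_objective_factory(sweeps, patch, g_single, E_K, filter, h_max)
  resfn <- gating_residual_factory(sweeps, patch, g_single, E_K, filter, h_max)
  lo <- bounds$lower; up <- bounds$upper
  sw <- pso_minimize(fn, lo, up, swarm_size, n_iter, seed)
  starts <- sw$swarm_best[seq_len(min(n_polish, nrow(sw$swarm_best))), ,
                          drop = FALSE]
  scl2 <- max(abs(unlist(lapply(sweeps, function(s) s$i_out))))^2
  best <- list(par = sw$par, value = sw$value)
  for (i in seq_len(nrow(starts))) {
    loc <- tryCatch(
      minpack.lm::nls.lm(log(starts[i, ]), fn = resfn,
                         lower = log(lo), upper = log(up),
                         control = minpack.lm::nls.lm.control(
                           maxiter = polish_maxit, ftol = 1e-15,
                           ptol = 1e-15, gtol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(loc) && is.finite(loc$deviance) &&
        loc$deviance * scl2 < best$value)
      best <- list(par = exp(loc$par), value = loc$deviance * scl2)
  }
  par <- setNames(best$par, names(lo))
  rp <- rate_params(par["alpha1"], par["m"], par["beta1"], par["n"],
                    par["A"], par["B"])
  pop <- channel_population(N = par[["N"]], g = g_single, E_K = E_K)
  resid <- lapply(sweeps, function(s) {
    sim <- simulate_voltage_clamp(s[, c("t", "v_cmd")], patch, pop, rp,
                                  filter = filter, h_max = h_max)
    s$i_out - sim$i_out
  })
  structure(list(parameters = rp, N = par[["N"]], par = par,
                 objective = best$value, history = sw$history,
                 swarm_size = swarm_size, n_iter = n_iter, seed = seed,
                 residuals = resid),
            class = "fit_result")
}

#' Per-cell channel-count fit
#'
#' Bounded scalar minimisation (golden-section via `optimize`) of the
#' quadratic relative difference between steady-state current simulations
#' and measurements, `sum(((I_ss_sim(N) - I_ss_meas)/I_ss_meas)^2)`, over
#' the steps whose measured steady-state current exceeds `current_floor`.
#' The steady-state simulation solves the clamped circuit self-consistently.
#'
#' @param sweeps voltage-clamp sweep family with `step_level` attributes
#' @param patch [patch_params()]
#' @param rates [rate_params()]
#' @param interval search interval for N, `c(lower, upper)`
#' @param g_single single-channel conductance (S)
#' @param E_K reversal potential (V)
#' @param ss_frac fraction of the step tail averaged as "steady state"
#'   (default last 10 %)
#' @param current_floor minimum |I_ss| (A) for a step to enter the objective
#' @return fitted `N` (scalar)
#' @export
fit_channel_count <- function(sweeps, patch, rates, interval = c(1000, 50000),
                              g_single = 12e-12, E_K = -0.073,
                              ss_frac = 0.1, current_floor = 2e-11) {
  if (length(interval) != 2 || interval[1] >= interval[2])
    stop("search interval must be c(lower, upper) with lower < upper")
  lev <- vapply(sweeps, function(s) attr(s, "step_level"), numeric(1))
  imeas <- vapply(sweeps, function(s) {
    tmax <- max(s$t)
    tw <- tmax - ss_frac * (tmax - min(s$t))
    mean(s$i_out[s$t >= tw])
  }, numeric(1))
  keep <- abs(imeas) >= current_floor
  if (!any(keep)) stop("all steps are below the steady-state current floor")
  lev <- lev[keep]; imeas <- imeas[keep]
  obj <- function(N) {
    pop <- channel_population(N = N, g = g_single, E_K = E_K)
    isim <- vapply(lev, steady_state_current, numeric(1),
                   patch = patch, channels = pop, rates = rates)
    sum(((isim - imeas) / imeas)^2)
  }
  optimize(obj, interval, tol = 1e-4)$minimum
}

#' Refine whole-cell patch parameters
#'
#' Local optimisation (Nelder-Mead in log-parameter space) of
#' `(R_B, C_M, R_S, R_seal)` against the capacitive transients and
#' steady-state segments of sub-threshold activation sweeps (steps at or
#' below `passive_below`, where the channels carry negligible current), from
#' the given starting values.
#'
#' @param sweeps voltage-clamp sweep family with `step_level` attributes
#' @param start starting [patch_params()]
#' @param passive_below most positive step level (V) included in the fit
#' @param filter [filter_spec()] matching the sweeps' filtering, or NULL
#' @param channels,rates optional channel model included in the candidate
#'   simulations; without it the sub-threshold channel current (a few pA
#'   through the tail of the activation curve) biases the leak estimates
#' @param maxit optimiser iteration cap
#' @return fitted [patch_params()] (background reversal kept from `start`)
#' @export
fit_patch_parameters <- function(sweeps, start, passive_below = -0.070,
                                 filter = filter_spec(), channels = NULL,
                                 rates = NULL, maxit = 100) {
  stopifnot(inherits(start, "patch_params"))
  lev <- vapply(sweeps, function(s) attr(s, "step_level"), numeric(1))
  sel <- which(lev <= passive_below + 1e-12)
  if (length(sel) < 2) stop("need at least two sub-threshold sweeps")
  protos <- lapply(sweeps[sel], function(s) s[, c("t", "v_cmd")])
  targets <- unlist(lapply(sweeps[sel], function(s) s$i_out))
  scl <- max(abs(targets))
  resfn <- function(lp) {
    pp <- patch_params(C_M = exp(lp[2]), R_S = exp(lp[3]),
                       R_seal = exp(lp[4]), R_B = exp(lp[1]),
                       E_VHEK = start$E_VHEK)
    sim <- unlist(lapply(protos, function(pr)
      simulate_voltage_clamp(pr, pp, channels = channels, rates = rates,
                             filter = filter)$i_out))
    (sim - targets) / scl
  }
  p0 <- log(c(start$R_B, start$C_M, start$R_S, start$R_seal))
  fit <- minpack.lm::nls.lm(p0, fn = resfn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = maxit, ftol = 1e-15, ptol = 1e-15))
  patch_params(C_M = exp(fit$par[2]), R_S = exp(fit$par[3]),
               R_seal = exp(fit$par[4]), R_B = exp(fit$par[1]),
               E_VHEK = start$E_VHEK)
}

#' Serialize a fit result with provenance
#'
#' @param fit a `fit_result` from [fit_gating_parameters()]
#' @param path output JSON path
#' @export
write_fit_result <- function(fit, path) {
  obj <- list(parameters = as.list(fit$par),
              objective = fit$objective,
              swarm_size = fit$swarm_size, n_iter = fit$n_iter,
              seed = fit$seed,
              package_version = as.character(packageVersion("oepcsim")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
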